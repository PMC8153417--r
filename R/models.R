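#' Names of the five arbitration model variants
#'
#' `Arb` is the base model (shared learning rate, fixed exploitation);
#' `Arb_a` splits the learning rate into `alpha_mb`/`alpha_mf`; the
#' `Arb_a_t*` variants additionally make the degree of exploitation a
#' function of the model choice probability (logistic, linear, and
#' reliability-weighted respectively).
#'
#' @return Character vector of model names.
#' @export
model_names <- function() c("Arb", "Arb_a", "Arb_a_t1", "Arb_a_t2", "Arb_a_t3")

#' Model specification
#'
#' Parameter names, box bounds, and the exploitation rule of one of the
#' five arbitration variants. Every parameter is lower-bounded at 0;
#' learning rates (and the logistic midpoint `c4`) are upper-bounded at 1.
#' The upper caps on exploitation parameters (`tau`, `c*` at 50) and rate
#' amplitudes (`A_*` at 5) are configurable fitting-box defaults.
#'
#' @param name a model name (see [model_names()]), or an existing spec
#'   (returned unchanged).
#' @param tau_upper,amp_upper upper caps of the exploitation and amplitude
#'   boxes.
#' @return A list with class `"model_spec"`: `name`, `params`, `lower`,
#'   `upper`, `variant`, `k` (free-parameter count).
#' @export
model_spec <- function(name, tau_upper = 50, amp_upper = 5) {
  if (inherits(name, "model_spec")) return(name)
  name <- match.arg(name, model_names())
  base <- c("eta", "A_beta", "A_gamma")
  def <- switch(name,
    Arb      = list(params = c("alpha", base, "tau"), variant = "fixed"),
    Arb_a    = list(params = c("alpha_mb", "alpha_mf", base, "tau"),
                    variant = "fixed"),
    Arb_a_t1 = list(params = c("alpha_mb", "alpha_mf", base,
                               "c1", "c2", "c3", "c4"), variant = "logistic"),
    Arb_a_t2 = list(params = c("alpha_mb", "alpha_mf", base, "c"),
                    variant = "linear"),
    Arb_a_t3 = list(params = c("alpha_mb", "alpha_mf", base,
                               "tau_mb", "tau_mf"), variant = "weighted"))
  upper_of <- function(p) switch(p,
    alpha = , alpha_mb = , alpha_mf = , eta = , c4 = 1,
    A_beta = , A_gamma = amp_upper,
    tau_upper)
  upper <- vapply(def$params, upper_of, numeric(1))
  lower <- setNames(rep(0, length(def$params)), def$params)
  structure(list(name = name, params = def$params, lower = lower,
                 upper = upper, variant = def$variant,
                 k = length(def$params)), class = "model_spec")
}

#' Expand model parameters into the agent's canonical form
#'
#' Maps a named parameter vector of any model variant onto the canonical
#' agent parameters: the two learning rates (`Arb` shares one `alpha` for
#' both systems), the reliability learning rate, the two rate amplitudes,
#' and an [exploitation_spec()]. This shared expansion is what makes the
#' nesting relations exact: `Arb_a_t3` with `tau_mb = tau_mf` reproduces
#' `Arb_a`, and `Arb_a` with `alpha_mb = alpha_mf` reproduces `Arb`.
#'
#' @param model a model name or `"model_spec"`.
#' @param par named numeric vector of that model's parameters.
#' @return `list(alpha_mb, alpha_mf, eta, A_beta, A_gamma, expl)`.
#' @export
expand_params <- function(model, par) {
  spec <- model_spec(model)
  miss <- setdiff(spec$params, names(par))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  p <- as.list(par[spec$params])
  expl <- switch(spec$variant,
    fixed = exploitation_spec("fixed", tau = p$tau),
    logistic = exploitation_spec("logistic", c1 = p$c1, c2 = p$c2,
                                 c3 = p$c3, c4 = p$c4),
    linear = exploitation_spec("linear", c = p$c),
    weighted = exploitation_spec("weighted", tau_mb = p$tau_mb,
                                 tau_mf = p$tau_mf))
  list(alpha_mb = p$alpha_mb %||% p$alpha,
       alpha_mf = p$alpha_mf %||% p$alpha,
       eta = p$eta, A_beta = p$A_beta, A_gamma = p$A_gamma, expl = expl)
}

#' Validate parameters against a model's bounds
#'
#' @inheritParams expand_params
#' @return The parameter vector, invisibly; errors on violations.
#' @export
validate_params <- function(model, par) {
  spec <- model_spec(model)
  p <- par[spec$params]
  if (anyNA(p)) stop("missing parameter(s): ",
                     paste(spec$params[is.na(p)], collapse = ", "))
  low <- p < spec$lower | p > spec$upper
  if (any(low)) stop("parameter(s) out of bounds: ",
                     paste(spec$params[low], collapse = ", "))
  if (spec$variant == "logistic" && p["c2"] < p["c1"])
    stop("logistic exploitation requires c2 >= c1")
  invisible(par)
}

# --- box transforms for the unconstrained simplex search ------------------
# theta = lower + (upper - lower) * plogis(z) maps R onto the open box; the
# logistic model's c2 is fit as c2 = c1 + (upper - c1) * plogis(z) so that
# c2 >= c1 holds throughout the search.

transform_params <- function(spec, z) {
  th <- spec$lower + (spec$upper - spec$lower) * plogis(z)
  names(th) <- spec$params
  if (spec$variant == "logistic") {
    i1 <- match("c1", spec$params); i2 <- match("c2", spec$params)
    th[i2] <- th[i1] + (spec$upper[i2] - th[i1]) * plogis(z[i2])
  }
  th
}

# random interior restart points, drawn on each parameter's natural scale
# (log-uniform for the scale-like exploitation parameters, whose plausible
# values sit far below their box cap) and mapped to the search space
draw_starts <- function(spec, n) {
  draw <- function(p) switch(p,
    alpha = , alpha_mb = , alpha_mf = , eta = , c4 = runif(n, 0.02, 0.98),
    A_beta = , A_gamma = runif(n, 0.05, 3),
    c3 = runif(n, 0.5, 10),
    exp(runif(n, log(0.02), log(5))))  # tau, tau_mb, tau_mf, c, c1, c2 gap
  th <- vapply(spec$params, draw, numeric(n))
  if (n == 1L) th <- matrix(th, nrow = 1L,
                            dimnames = list(NULL, spec$params))
  if (spec$variant == "logistic")
    th[, "c2"] <- th[, "c1"] + th[, "c2"]
  t(apply(th, 1L, function(p) untransform_params(spec, p)))
}

untransform_params <- function(spec, par) {
  th <- par[spec$params]
  z <- qlogis((th - spec$lower) / (spec$upper - spec$lower))
  if (spec$variant == "logistic") {
    z["c2"] <- qlogis((th["c2"] - th["c1"]) /
                        (spec$upper["c2"] - th["c1"]))
  }
  unname(z)
}
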