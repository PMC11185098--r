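#' Parameter set of a DLC-IRT model
#'
#' Collects every free parameter of a model variant on its natural scale:
#' item difficulties `beta` (named by item id), the general engagement
#' intercept `alpha0`, item-specific intercept offsets `alpha_item`,
#' covariate coefficients `gamma` (named by covariate), interaction
#' coefficients `gamma_int` (named `"a:b"`), the ability variance
#' `var_theta`, the engagement-threshold variance `sigma2_psi` with
#' covariance `cov_psi_theta`, and optionally a shared free guessing
#' probability `z_free`.
#'
#' @param beta named numeric vector of item difficulties (logits).
#' @param alpha0 general engagement intercept.
#' @param alpha_item named numeric vector of item-specific intercept offsets.
#' @param gamma named numeric vector of covariate coefficients.
#' @param gamma_int named numeric vector of interaction coefficients.
#' @param var_theta variance of theta (> 0).
#' @param sigma2_psi variance of psi (>= 0).
#' @param cov_psi_theta covariance of psi and theta; the implied 2x2
#'   covariance matrix must be positive semidefinite.
#' @param z_free optional shared guessing probability in (0, 1).
#' @return object of class `dlc_params`.
#' @export
dlc_params <- function(beta, alpha0 = NULL, alpha_item = numeric(),
                       gamma = numeric(), gamma_int = numeric(),
                       var_theta = 1, sigma2_psi = 0, cov_psi_theta = 0,
                       z_free = NULL) {
  stopifnot(is.numeric(beta), length(beta) >= 1, all(is.finite(beta)))
  if (is.null(names(beta))) names(beta) <- as.character(seq_along(beta))
  if (var_theta <= 0) stop("var_theta must be > 0", call. = FALSE)
  if (sigma2_psi < 0) stop("sigma2_psi must be >= 0", call. = FALSE)
  latent_chol(var_theta, sigma2_psi, cov_psi_theta)  # PSD check
  if (!is.null(z_free) && (z_free <= 0 || z_free >= 1))
    stop("z_free must lie in (0, 1)", call. = FALSE)
  structure(list(beta = beta, alpha0 = alpha0, alpha_item = alpha_item,
                 gamma = gamma, gamma_int = gamma_int,
                 var_theta = var_theta, sigma2_psi = sigma2_psi,
                 cov_psi_theta = cov_psi_theta, z_free = z_free),
            class = "dlc_params")
}

#' @export
print.dlc_params <- function(x, ...) {
  cat("DLC-IRT parameter set\n")
  cat("  beta:      ", paste(sprintf("%s=%.3f", names(x$beta), x$beta),
                             collapse = " "), "\n")
  if (!is.null(x$alpha0)) cat("  alpha0:    ", format(x$alpha0), "\n")
  if (length(x$alpha_item))
    cat("  alpha_item:", paste(sprintf("%s=%.3f", names(x$alpha_item),
                                       x$alpha_item), collapse = " "), "\n")
  if (length(x$gamma))
    cat("  gamma:     ", paste(sprintf("%s=%.3f", names(x$gamma), x$gamma),
                               collapse = " "), "\n")
  if (length(x$gamma_int))
    cat("  gamma_int: ", paste(sprintf("%s=%.3f", names(x$gamma_int),
                                       x$gamma_int), collapse = " "), "\n")
  cat("  var_theta: ", format(x$var_theta),
      " sigma2_psi:", format(x$sigma2_psi),
      " cov_psi_theta:", format(x$cov_psi_theta), "\n")
  if (!is.null(x$z_free)) cat("  z_free:    ", format(x$z_free), "\n")
  invisible(x)
}

# ---- unconstrained packing ---------------------------------------------
# Order: beta (J) | log var_theta (if free) | alpha0, alpha_item, gamma,
# gamma_int (mixture families) | log sigma2_psi, atanh(rho) (dlc_tl) |
# logit z_free (equal_free).

par_names <- function(spec, item_ids) {
  nm <- paste0("beta:", item_ids)
  if (spec$theta_variance_mode == "free") nm <- c(nm, "var_theta")
  if (spec$family != "rasch") {
    nm <- c(nm, "alpha0",
            if (length(spec$intercept_items))
              paste0("alpha_item:", spec$intercept_items),
            paste0("gamma:", spec$covariates),
            if (length(spec$interactions))
              paste0("gamma_int:", spec$interactions))
  }
  if (spec$family == "dlc_tl") nm <- c(nm, "sigma2_psi", "rho_psi_theta")
  if (spec$z_mode == "equal_free") nm <- c(nm, "z_free")
  nm
}

pack_params <- function(spec, params, item_ids) {
  u <- unname(params$beta[item_ids])
  if (anyNA(u)) stop("params$beta must be named by every item id", call. = FALSE)
  if (spec$theta_variance_mode == "free") u <- c(u, log(params$var_theta))
  if (spec$family != "rasch") {
    ai <- rep(0, length(spec$intercept_items))
    names(ai) <- spec$intercept_items
    if (length(params$alpha_item)) {
      keep <- intersect(names(params$alpha_item), spec$intercept_items)
      ai[keep] <- params$alpha_item[keep]
    }
    gm <- rep(0, length(spec$covariates)); names(gm) <- spec$covariates
    if (length(params$gamma)) {
      keep <- intersect(names(params$gamma), spec$covariates)
      gm[keep] <- params$gamma[keep]
    }
    gi <- rep(0, length(spec$interactions)); names(gi) <- spec$interactions
    if (length(params$gamma_int)) {
      nn <- normalize_interactions(names(params$gamma_int))
      keep <- nn %in% spec$interactions
      gi[nn[keep]] <- params$gamma_int[keep]
    }
    u <- c(u, params$alpha0 %||% 0, unname(ai), unname(gm), unname(gi))
  }
  if (spec$family == "dlc_tl") {
    s2 <- max(params$sigma2_psi, 1e-8)
    rho <- params$cov_psi_theta / sqrt(params$var_theta * s2)
    rho <- max(min(rho, 1 - 1e-10), -1 + 1e-10)
    u <- c(u, log(s2), atanh(rho))
  }
  if (spec$z_mode == "equal_free") {
    z <- params$z_free %||% 0.25
    u <- c(u, stats::qlogis(z))
  }
  u
}

unpack_params <- function(spec, u, item_ids) {
  J <- length(item_ids)
  pos <- 0L
  take <- function(n) { v <- u[pos + seq_len(n)]; pos <<- pos + n; v }
  beta <- take(J); names(beta) <- item_ids
  var_theta <- if (spec$theta_variance_mode == "free") exp(take(1L)) else 1
  alpha0 <- NULL; alpha_item <- numeric(); gamma <- numeric(); gamma_int <- numeric()
  if (spec$family != "rasch") {
    alpha0 <- take(1L)
    alpha_item <- take(length(spec$intercept_items))
    names(alpha_item) <- spec$intercept_items
    gamma <- take(length(spec$covariates)); names(gamma) <- spec$covariates
    gamma_int <- take(length(spec$interactions))
    names(gamma_int) <- spec$interactions
  }
  sigma2_psi <- 0; cov_psi_theta <- 0
  if (spec$family == "dlc_tl") {
    sigma2_psi <- exp(take(1L))
    rho <- tanh(take(1L))
    cov_psi_theta <- rho * sqrt(var_theta * sigma2_psi)
  }
  z_free <- if (spec$z_mode == "equal_free") stats::plogis(take(1L)) else NULL
  stopifnot(pos == length(u))
  dlc_params(beta = beta, alpha0 = alpha0, alpha_item = alpha_item,
             gamma = gamma, gamma_int = gamma_int, var_theta = var_theta,
             sigma2_psi = sigma2_psi, cov_psi_theta = cov_psi_theta,
             z_free = z_free)
}

# Jacobian d(natural)/d(unconstrained) for the delta-method SEs. Natural
# parameters reported: beta, var_theta, alpha0/alpha_item/gamma/gamma_int,
# sigma2_psi, cov_psi_theta, z_free — same order as the packed vector.
par_jacobian <- function(spec, u, item_ids) {
  n <- length(u)
  Jac <- diag(n)
  nm <- par_names(spec, item_ids)
  if (spec$theta_variance_mode == "free") {
    i <- match("var_theta", nm)
    Jac[i, i] <- exp(u[i])                      # var = exp(lvt)
  }
  if (spec$family == "dlc_tl") {
    is2 <- match("sigma2_psi", nm)
    irho <- match("rho_psi_theta", nm)
    s2 <- exp(u[is2]); rho <- tanh(u[irho])
    vt <- if (spec$theta_variance_mode == "free")
      exp(u[match("var_theta", nm)]) else 1
    Jac[is2, is2] <- s2                         # sigma2 = exp(lsig)
    # cov = rho * sqrt(vt * s2) replaces the rho row in the natural vector
    Jac[irho, ] <- 0
    Jac[irho, irho] <- sqrt(vt * s2) * (1 - rho^2)
    Jac[irho, is2] <- rho * sqrt(vt * s2) / 2
    if (spec$theta_variance_mode == "free")
      Jac[irho, match("var_theta", nm)] <- rho * sqrt(vt * s2) / 2
  }
  if (spec$z_mode == "equal_free") {
    iz <- match("z_free", nm)
    z <- stats::plogis(u[iz])
    Jac[iz, iz] <- z * (1 - z)
  }
  Jac
}

natural_par_names <- function(spec, item_ids) {
  nm <- par_names(spec, item_ids)
  nm[nm == "rho_psi_theta"] <- "cov_psi_theta"
  nm
}

#' Serialize / deserialize a parameter set as JSON
#'
#' @param params a `dlc_params`.
#' @param path file path.
#' @return `read_params_json` returns a `dlc_params`; `write_params_json`
#'   returns `path` invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "dlc_params"))
  x <- unclass(params)
  x$beta <- as.list(x$beta)
  x$alpha_item <- as.list(x$alpha_item)
  x$gamma <- as.list(x$gamma)
  x$gamma_int <- as.list(x$gamma_int)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_named <- function(v) if (is.null(v) || !length(v)) numeric() else unlist(v)
  dlc_params(beta = as_named(x$beta), alpha0 = x$alpha0,
             alpha_item = as_named(x$alpha_item), gamma = as_named(x$gamma),
             gamma_int = as_named(x$gamma_int), var_theta = x$var_theta,
             sigma2_psi = x$sigma2_psi, cov_psi_theta = x$cov_psi_theta,
             z_free = x$z_free)
}
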