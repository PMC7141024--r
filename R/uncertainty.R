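#' First-order Taylor-series propagation of TP uncertainty
#'
#' Propagates measurement uncertainty (on the Glx-Phe difference, or on Glx
#' and Phe separately) and parameter uncertainty (beta and the TDFs) through
#' the closed-form TP equations using a first-order Taylor expansion:
#' `sd(TP) = sqrt(sum((dTP/dx_i)^2 * sd_i^2))` with analytically coded
#' partial derivatives. All inputs are treated as independent (no published
#' covariance structure exists for them).
#'
#' For equation 1 with denominator `L = tdf_base`, the partials are `1/L` for
#' the Glx-Phe difference, `-1/L` for beta, and `-(delta - beta)/L^2` for the
#' TDF; equation 3 adds a `-1/L` term for the consumer TDF, and equation 4's
#' denominator partial involves the consumer TDF instead.
#'
#' @param framework A [tdf_framework()] (carries beta/TDF values and SDs).
#' @param delta Numeric vector: Glx-Phe difference (or multi-AA difference for
#'   equation 2), permil.
#' @param delta_sd SD of `delta` (permil); mutually exclusive with
#'   `glx_sd`/`phe_sd`.
#' @param glx_sd,phe_sd Component SDs; combined as `sqrt(glx_sd^2 + phe_sd^2)`.
#' @return Numeric vector of TP standard deviations.
#' @seealso [propagate_mc()] for the Monte-Carlo cross-check.
#' @export
#' @examples
#' fw <- default_frameworks()$chikaraishi_single
#' propagate_taylor(fw, delta = 12.40, delta_sd = 0) # 0.2213...
propagate_taylor <- function(framework, delta, delta_sd = 0,
                             glx_sd = NULL, phe_sd = NULL) {
  stopifnot(inherits(framework, "tdf_framework"))
  delta_sd <- resolve_delta_sd(delta_sd, glx_sd, phe_sd, missing(delta_sd))
  b <- framework$beta
  lam <- framework$tdf_base
  eq <- framework$equation_id
  var <- switch(as.character(eq),
    "1" = ,
    "2" = (delta_sd^2 + b$sd^2) / lam$value^2 +
      (delta - b$value)^2 * lam$sd^2 / lam$value^4,
    "3" = {
      tc <- framework$tdf_consumer
      (delta_sd^2 + b$sd^2 + tc$sd^2) / lam$value^2 +
        (delta - tc$value - b$value)^2 * lam$sd^2 / lam$value^4
    },
    "4" = {
      tc <- framework$tdf_consumer
      (delta_sd^2 + b$sd^2 + lam$sd^2) / tc$value^2 +
        (delta - lam$value - b$value)^2 * tc$sd^2 / tc$value^4
    }
  )
  if (any(var < 0)) abort("Internal error: negative variance contribution.")
  sqrt(var)
}

resolve_delta_sd <- function(delta_sd, glx_sd, phe_sd, delta_sd_missing) {
  component <- !is.null(glx_sd) || !is.null(phe_sd)
  if (component) {
    if (!delta_sd_missing) {
      abort("Give either delta_sd or glx_sd/phe_sd, not both.",
        class = "csiatp_configuration_error"
      )
    }
    if (is.null(glx_sd) || is.null(phe_sd)) {
      abort("Component mode needs both glx_sd and phe_sd.",
        class = "csiatp_configuration_error"
      )
    }
    delta_sd <- sqrt(glx_sd^2 + phe_sd^2)
  }
  if (any(delta_sd < 0)) abort("SDs must be >= 0.")
  delta_sd
}

#' Monte-Carlo propagation of TP uncertainty (validation oracle)
#'
#' Estimates the TP standard deviation by drawing every uncertain input from
#' an independent Gaussian and recomputing TP for each draw. This is the
#' package's independent check on [propagate_taylor()]: for equations linear
#' in their uncertain inputs (denominator SD zero) the two agree exactly up
#' to Monte-Carlo error; with uncertainty on the denominator TDF the Taylor
#' result is a first-order approximation to the ratio distribution's SD.
#'
#' Draws that make the denominator TDF non-positive are rejected and redrawn;
#' the count is reported and a warning raised when rejections exceed 1%.
#'
#' @inheritParams propagate_taylor
#' @param n_draws Number of draws, `>= 1e4`.
#' @param seed Integer seed (mandatory: results must be reproducible).
#' @return A single TP SD (`delta` must be scalar here), with attributes
#'   `n_rejected` and `tp_mean`.
#' @export
propagate_mc <- function(framework, delta, delta_sd = 0,
                         glx_sd = NULL, phe_sd = NULL,
                         n_draws = 1e5, seed) {
  stopifnot(inherits(framework, "tdf_framework"), length(delta) == 1)
  if (missing(seed)) abort("propagate_mc requires an explicit seed.")
  if (n_draws < 1e4) abort("n_draws must be >= 1e4.")
  delta_sd <- resolve_delta_sd(delta_sd, glx_sd, phe_sd, missing(delta_sd))

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    b <- framework$beta
    lam <- framework$tdf_base
    tc <- framework$tdf_consumer
    draw_pos <- function(value, sd, n) {
      # rejection sampling keeps the denominator TDF strictly positive
      x <- rnorm(n, value, sd)
      rejected <- 0L
      while (any(x <= 0)) {
        idx <- which(x <= 0)
        rejected <- rejected + length(idx)
        x[idx] <- rnorm(length(idx), value, sd)
      }
      list(x = x, rejected = rejected)
    }
    d_draw <- rnorm(n_draws, delta, delta_sd)
    b_draw <- rnorm(n_draws, b$value, b$sd)
    rejected <- 0L
    eq <- framework$equation_id
    tp <- switch(as.character(eq),
      "1" = ,
      "2" = {
        lam_d <- draw_pos(lam$value, lam$sd, n_draws)
        rejected <- lam_d$rejected
        (d_draw - b_draw) / lam_d$x + 1
      },
      "3" = {
        lam_d <- draw_pos(lam$value, lam$sd, n_draws)
        rejected <- lam_d$rejected
        tc_draw <- rnorm(n_draws, tc$value, tc$sd)
        (d_draw - tc_draw - b_draw) / lam_d$x + 2
      },
      "4" = {
        tc_d <- draw_pos(tc$value, tc$sd, n_draws)
        rejected <- tc_d$rejected
        lam_draw <- rnorm(n_draws, lam$value, lam$sd)
        (d_draw - lam_draw - b_draw) / tc_d$x + 2
      }
    )
    if (rejected > 0.01 * n_draws) {
      warn(paste0(
        "Monte-Carlo propagation rejected ", rejected,
        " non-positive denominator draws (> 1% of ", n_draws, ")."
      ))
    }
    out <- stats::sd(tp)
    attr(out, "n_rejected") <- rejected
    attr(out, "tp_mean") <- mean(tp)
    out
  })
}
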