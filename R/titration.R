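#' Parse dilution factors written as powers
#'
#' Accepts plain decimals (`"0.001"`), or power notation `"2^-10"` /
#' `"10^-5"` as commonly written for serial dilution schedules.
#'
#' @param x Character or numeric vector.
#' @return Numeric dilution factors.
#' @examples
#' parse_dilution(c("2^-10", "10^-5", "0.25"))
#' @export
parse_dilution <- function(x) {
  if (is.numeric(x)) return(x)
  vapply(as.character(x), function(s) {
    s <- gsub("\\s", "", s)
    if (grepl("^[0-9.eE+-]+$", s)) return(as.numeric(s))
    m <- regmatches(s, regexec("^([0-9.]+)\\^(-?[0-9.]+)$", s))[[1]]
    if (length(m) == 3) return(as.numeric(m[2])^as.numeric(m[3]))
    stop(sprintf("cannot parse dilution '%s'", s))
  }, numeric(1), USE.NAMES = FALSE)
}

#' End-point dilution titration series
#'
#' One titration: at each step `i`, `wells[i]` replicate wells were
#' inoculated at dilution `dilution[i]` (relative to step 0) and
#' `positives[i]` of them showed infection.
#'
#' @param dilution Dilution factors in `(0, 1]`, strictly decreasing;
#'   power strings like `"2^-10"` are accepted.
#' @param positives Positive wells per step.
#' @param wells Total wells per step.
#' @param label Optional series label.
#' @param conditions Optional metadata (temperature, medium, ...).
#' @return A `titration_series`.
#' @examples
#' titration_series(2^-(9:12), c(15, 12, 2, 0), 15)
#' @export
titration_series <- function(dilution, positives, wells, label = NULL,
                             conditions = list()) {
  dilution <- parse_dilution(dilution)
  if (length(wells) == 1L) wells <- rep(wells, length(dilution))
  stopifnot(length(positives) == length(dilution),
            length(wells) == length(dilution),
            all(dilution > 0), all(dilution <= 1),
            all(positives >= 0), all(positives <= wells), all(wells >= 1))
  if (is.unsorted(rev(dilution), strictly = TRUE)) {
    stop("`dilution` must be strictly decreasing")
  }
  structure(list(steps = data.frame(dilution = dilution,
                                    positives = as.integer(positives),
                                    wells = as.integer(wells)),
                 label = label, conditions = conditions),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series%s:\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Probability of detecting virus in a well
#'
#' Under Poisson partitioning, the number of infectious units in a well at
#' dilution `d` is Poisson with mean `a * d`, so the well is positive with
#' probability `1 - exp(-a * d)`.
#'
#' @param a Expected infectious units per well at dilution 1, `>= 0`.
#' @param d Dilution factor, `>= 0`.
#' @return Detection probability (vectorised).
#' @examples
#' detection_probability(log(2), 1)   # 0.5 by construction
#' @export
detection_probability <- function(a, d) {
  if (any(a < 0) || any(d < 0)) stop("`a` and `d` must be non-negative")
  1 - exp(-a * d)
}

# Binomial log-likelihood of the detection curve at log(a).
titration_loglik <- function(log_a, steps) {
  a <- exp(log_a)
  lam <- a * steps$dilution
  # log(1 - exp(-lam)) computed stably for small lam
  lp <- ifelse(lam < 1e-8, log(lam) + log1p(-lam / 2), log(-expm1(-lam)))
  sum(steps$positives * lp - (steps$wells - steps$positives) * lam)
}

#' Fit the Poisson detection model to a titration series
#'
#' Estimates `a`, the expected infectious units per well at step 0, from
#' the per-step positive counts.  The default is maximum likelihood under
#' the binomial model `k_i ~ Binomial(n_i, 1 - exp(-a d_i))`, whose
#' log-likelihood is strictly concave in `a`; the 95% confidence interval
#' comes from the profile likelihood (deviance drop of `qchisq(level, 1)`,
#' bisection in `log a`).  `method = "lsq"` instead minimises the squared
#' deviation of the observed positive fractions from the detection curve,
#' with a seeded parametric-bootstrap percentile interval.
#'
#' @param series A [titration_series()].
#' @param method `"ml"` (default) or `"lsq"`.
#' @param level Confidence level (default 0.95).
#' @param boot_reps Bootstrap replicates for the least-squares interval.
#' @param seed Seed for the bootstrap.
#' @return A `titration_fit` with `a_hat`, `ci95`, `tcid50_dilution`
#'   (`= log(2) / a_hat`), `method` and diagnostics.
#' @examples
#' fit_titration(titration_series(2^-(9:12), c(15, 12, 2, 0), 15))
#' @export
fit_titration <- function(series, method = c("ml", "lsq"), level = 0.95,
                          boot_reps = 1999, seed = 0) {
  method <- match.arg(method)
  stopifnot(inherits(series, "titration_series"))
  st <- series$steps
  if (all(st$positives == st$wells)) {
    stop("all steps fully positive: `a` is unbounded above; ",
         "extend the series to deeper dilutions")
  }
  if (all(st$positives == 0)) {
    stop("no positive wells: `a` is unbounded below")
  }
  lo <- log(0.01 / max(st$dilution))
  hi <- log(1000 / min(st$dilution))
  estimate <- function(steps) {
    if (method == "ml") {
      opt <- stats::optimize(titration_loglik, c(lo, hi), steps = steps,
                             maximum = TRUE, tol = 1e-10)
      exp(opt$maximum)
    } else {
      obj <- function(log_a) {
        p <- 1 - exp(-exp(log_a) * steps$dilution)
        sum((steps$positives / steps$wells - p)^2)
      }
      # the squared-error surface can have shoulders; locate the basin on
      # a coarse grid before polishing
      grid <- seq(lo, hi, length.out = 400)
      best <- grid[which.min(vapply(grid, obj, numeric(1)))]
      span <- (hi - lo) / 399
      exp(stats::optimize(obj, c(best - 2 * span, best + 2 * span),
                          tol = 1e-10)$minimum)
    }
  }
  a_hat <- estimate(st)
  if (method == "ml") {
    ll_max <- titration_loglik(log(a_hat), st)
    drop <- stats::qchisq(level, 1) / 2
    dev <- function(log_a) titration_loglik(log_a, st) - (ll_max - drop)
    ci <- c(NA_real_, NA_real_)
    ci[1] <- if (dev(lo) < 0) {
      exp(stats::uniroot(dev, c(lo, log(a_hat)), tol = 1e-6)$root)
    } else {
      exp(lo)
    }
    ci[2] <- if (dev(hi) < 0) {
      exp(stats::uniroot(dev, c(log(a_hat), hi), tol = 1e-6)$root)
    } else {
      exp(hi)
    }
    diag <- list(loglik = ll_max)
  } else {
    boots <- with_seed(seed, {
      p_hat <- 1 - exp(-a_hat * st$dilution)
      vapply(seq_len(boot_reps), function(r) {
        k <- stats::rbinom(nrow(st), st$wells, p_hat)
        if (all(k == st$wells) || all(k == 0)) return(NA_real_)
        s2 <- st; s2$positives <- k
        estimate(s2)
      }, numeric(1))
    })
    ci <- unname(stats::quantile(boots, c((1 - level) / 2,
                                          1 - (1 - level) / 2),
                                 na.rm = TRUE))
    diag <- list(boot_failures = sum(is.na(boots)))
  }
  structure(list(a_hat = a_hat, ci95 = ci,
                 tcid50_dilution = log(2) / a_hat,
                 method = method, level = level, series = series,
                 diagnostics = diag),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf(
    "Titration fit (%s): a = %.4g infectious units/well at step 0\n",
    toupper(x$method), x$a_hat))
  cat(sprintf("  %.0f%% CI: [%.4g, %.4g]\n", 100 * x$level, x$ci95[1],
              x$ci95[2]))
  cat(sprintf("  TCID50 at dilution %.4g (= 2^%.2f = 10^%.2f)\n",
              x$tcid50_dilution, log2(x$tcid50_dilution),
              log10(x$tcid50_dilution)))
  invisible(x)
}

#' TCID50 dilution of a fitted titration
#'
#' The dilution at which the detection probability is exactly one half:
#' `1 - exp(-a * d) = 0.5` gives `d = ln 2 / a`.
#'
#' @param fit A `titration_fit`.
#' @return The TCID50 dilution (relative to step 0).
#' @export
tcid50 <- function(fit) {
  stopifnot(inherits(fit, "titration_fit"))
  log(2) / fit$a_hat
}

#' Bookkeeping needed to convert a titration fit into a burst size
#'
#' The fitted `a` is infectious units per well at titration step 0.  To
#' express it per producing cell one needs the dilution of step 0 relative
#' to the undiluted lysate, the inoculated volume per well, the total
#' lysate volume and the number of cells that produced it.  None of these
#' are inferable from the series itself, so they must be supplied
#' explicitly.
#'
#' @param well0_dilution Dilution of step 0 relative to the undiluted
#'   suspension (e.g. `1e-6`).
#' @param inoculum_volume Volume plated per well, ml.
#' @param suspension_volume Total lysate volume, ml (default 10: 3 ml
#'   inoculation volume plus 7 ml medium).
#' @param n_cells Number of seeded cells (default `2e6`).
#' @return A `burst_bookkeeping`.
#' @export
burst_bookkeeping <- function(well0_dilution, inoculum_volume,
                              suspension_volume = 10, n_cells = 2e6) {
  if (missing(inoculum_volume) || is.null(inoculum_volume)) {
    stop("`inoculum_volume` must be given explicitly (ml per well)")
  }
  stopifnot(well0_dilution > 0, well0_dilution <= 1, inoculum_volume > 0,
            suspension_volume > 0, n_cells > 0)
  structure(list(well0_dilution = well0_dilution,
                 inoculum_volume = inoculum_volume,
                 suspension_volume = suspension_volume,
                 n_cells = n_cells),
            class = "burst_bookkeeping")
}

#' Burst size: infectious units produced per cell
#'
#' Converts the fitted per-well expectation into infectious units per ml
#' of undiluted suspension (`a / (well0_dilution * inoculum_volume)`) and
#' then into units per producing cell; confidence-interval endpoints are
#' transformed identically (the map is linear in `a`).
#'
#' @param fit A `titration_fit`.
#' @param bookkeeping A [burst_bookkeeping()].
#' @return List with `burst`, `ci95`, `per_ml` and the bookkeeping used.
#' @export
burst_size <- function(fit, bookkeeping) {
  stopifnot(inherits(fit, "titration_fit"),
            inherits(bookkeeping, "burst_bookkeeping"))
  bk <- bookkeeping
  per_ml <- fit$a_hat / (bk$well0_dilution * bk$inoculum_volume)
  scale <- bk$suspension_volume / bk$n_cells /
    (bk$well0_dilution * bk$inoculum_volume)
  list(burst = fit$a_hat * scale, ci95 = fit$ci95 * scale,
       per_ml = per_ml, bookkeeping = bk)
}
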