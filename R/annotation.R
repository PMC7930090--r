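#' Virion classification rule
#'
#' Length/ellipticity thresholds separating virions from other
#' high-contrast objects (mostly near-circular granules and mitochondria
#' below 500 nm).  A mark is a virion iff
#' `min_length <= length <= max_length` and
#' `length / width >= min_ellipticity`, all bounds inclusive.
#'
#' @param min_length Minimum projected length, nm (default 700).
#' @param max_length Maximum projected length, nm (default 1500).
#' @param min_ellipticity Minimum length/width ratio (default 1.3).
#' @return A `classification_rule`.
#' @export
classification_rule <- function(min_length = 700, max_length = 1500,
                                min_ellipticity = 1.3) {
  stopifnot(min_length > 0, max_length > min_length, min_ellipticity >= 1)
  structure(list(min_length = min_length, max_length = max_length,
                 min_ellipticity = min_ellipticity),
            class = "classification_rule")
}

#' Ingest object marks
#'
#' Normalises a data frame of cross marks (centre, length, width, optional
#' angle).  Length and width are swapped wherever `width > length`, so the
#' stored convention `length >= width > 0` always holds.  Marks with
#' non-positive width are rejected with a diagnostic.
#'
#' @param marks Data frame with at least `length_nm` and `width_nm`
#'   columns; `center_x_px`, `center_y_px`, `angle_deg` are carried along
#'   if present.
#' @return The normalised data frame.
#' @export
as_object_marks <- function(marks) {
  marks <- as.data.frame(marks)
  if (nrow(marks) == 0) return(marks)
  stopifnot(all(c("length_nm", "width_nm") %in% names(marks)))
  bad <- !is.finite(marks$width_nm) | marks$width_nm <= 0 |
    !is.finite(marks$length_nm) | marks$length_nm <= 0
  if (any(bad)) {
    stop(sprintf("%d mark(s) have non-positive length or width", sum(bad)))
  }
  swap <- marks$width_nm > marks$length_nm
  if (any(swap)) {
    tmp <- marks$length_nm[swap]
    marks$length_nm[swap] <- marks$width_nm[swap]
    marks$width_nm[swap] <- tmp
    if ("angle_deg" %in% names(marks)) {
      marks$angle_deg[swap] <- (marks$angle_deg[swap] + 90) %% 180
    }
  }
  marks
}

#' Per-cell annotation container
#'
#' @param cell_id Identifier string.
#' @param hpi Infection time, hours post infection.
#' @param marks Data frame of object marks (see [as_object_marks()]).
#' @param mask Optional logical matrix cell mask.
#' @param approximate Flag for crowded late-time images where counting is
#'   approximate.
#' @return A `cell_annotation`.
#' @export
cell_annotation <- function(cell_id, hpi, marks, mask = NULL,
                            approximate = FALSE) {
  structure(list(cell_id = cell_id, hpi = hpi,
                 marks = as_object_marks(marks), mask = mask,
                 approximate = isTRUE(approximate)),
            class = "cell_annotation")
}

#' Classify marks into virions and other objects
#'
#' @param marks Data frame of marks (normalised on ingest).
#' @param rule A [classification_rule()].
#' @return Factor vector with levels `virion`, `other` (one per mark).
#' @examples
#' r <- classification_rule()
#' classify_marks(data.frame(length_nm = 1250, width_nm = 590), r)
#' @export
classify_marks <- function(marks, rule = classification_rule()) {
  marks <- as_object_marks(marks)
  if (nrow(marks) == 0) {
    return(factor(character(0), levels = c("virion", "other")))
  }
  ok <- marks$length_nm >= rule$min_length &
    marks$length_nm <= rule$max_length &
    marks$length_nm / marks$width_nm >= rule$min_ellipticity
  factor(ifelse(ok, "virion", "other"), levels = c("virion", "other"))
}

#' False-positive rate from non-infected control cells
#'
#' Control cells contain no true virions, so every mark classified as a
#' virion there is a false positive.  The rate is the pooled fraction of
#' control marks misclassified as virions, later scaled by the total mark
#' count of each infected cell to estimate its false-positive burden.
#'
#' @param controls List of `cell_annotation` objects from non-infected
#'   cells.
#' @param rule A [classification_rule()].
#' @return False positives per marked object (scalar in `[0, 1]`).
#' @export
false_positive_rate <- function(controls, rule = classification_rule()) {
  if (length(controls) == 0) stop("at least one control cell is required")
  stopifnot(all(vapply(controls, inherits, TRUE, "cell_annotation")))
  n_marks <- sum(vapply(controls, function(a) nrow(a$marks), 0))
  if (n_marks == 0) stop("empty controls: no marks to estimate a rate from")
  n_fp <- sum(vapply(controls, function(a) {
    sum(classify_marks(a$marks, rule) == "virion")
  }, 0))
  n_fp / n_marks
}

#' Probability that a randomly oriented rod projects below a length cutoff
#'
#' For a rod of true length `L` uniformly oriented in 3D, the projected
#' length is `L * sin(theta)` with `cos(theta)` uniform; the probability of
#' projecting below `min_length` is `1 - sqrt(1 - (min_length / L)^2)`.
#' For 1000-nm particles at the 700-nm cutoff this is 0.286 -- the roughly
#' 30% of virions expected to evade counting through orientation alone.
#'
#' @param true_length True particle length, nm.
#' @param min_length Projected-length cutoff, nm.
#' @return Miss probability in `[0, 1]` (vectorised).
#' @examples
#' orientation_miss_probability(1000, 700)
#' @export
orientation_miss_probability <- function(true_length, min_length) {
  stopifnot(all(true_length > 0), all(min_length >= 0))
  s <- min_length / true_length
  out <- ifelse(s >= 1, 1, 1 - sqrt(pmax(1 - pmin(s, 1)^2, 0)))
  if (any(s > 1)) {
    warning("`min_length` exceeds `true_length`: every orientation is missed")
  }
  out
}

#' Orientation miss probability for a prolate spheroid
#'
#' Unlike an idealised rod, a spheroid of length `L` and width `W`
#' projects to `sqrt(L^2 sin^2 theta + W^2 cos^2 theta)`, which never
#' falls below `W`.  Its probability of projecting below a cutoff `c`
#' equals the rod formula evaluated at
#' `(sqrt(L^2 - W^2), sqrt(c^2 - W^2))`: zero when `c <= W`, one when
#' `c >= L`.  The rod formula [orientation_miss_probability()] is the
#' `W -> 0` limit and is what a quick back-of-envelope estimate uses; the
#' spheroid form is the exact one for the phantom's particles.
#'
#' @param length_nm,width_nm True spheroid axes, nm.
#' @param min_length Projected-length cutoff, nm.
#' @return Miss probability in `[0, 1]`.
#' @export
spheroid_miss_probability <- function(length_nm, width_nm, min_length) {
  stopifnot(all(length_nm >= width_nm), all(width_nm > 0),
            all(min_length >= 0))
  s2 <- (min_length^2 - width_nm^2) / (length_nm^2 - width_nm^2)
  ifelse(min_length <= width_nm, 0,
         ifelse(min_length >= length_nm, 1, 1 - sqrt(1 - pmin(s2, 1))))
}

#' Effective projected-length cutoff of a classification rule
#'
#' The minimum projected length at which a particle of equatorial width
#' `width_nm` still satisfies both the length and the ellipticity
#' thresholds: `max(min_length, min_ellipticity * width_nm)`.  For the
#' default rule and 590-nm-wide virions the ellipticity bound (767 nm) is
#' the binding one.
#'
#' @param rule A [classification_rule()].
#' @param width_nm Particle width, nm.
#' @return Effective cutoff, nm.
#' @export
effective_min_projected_length <- function(rule, width_nm) {
  pmax(rule$min_length, rule$min_ellipticity * width_nm)
}

#' Count virions in one cell with the two-part uncertainty
#'
#' The count is the number of marks classified as virions.  Its uncertainty
#' adds two error sources: an expected false-positive burden
#' `fp_rate * n_marks_total` (the control misclassification rate scaled by
#' how much was marked), and an orientation undercount.  With miss
#' probability `p`, counting is a thinning of the true population, so the
#' expected number of missed virions given `n` counted is `n * p / (1 - p)`
#' (`miss_mode = "inversion"`, the default); `miss_mode = "direct"` uses
#' the cruder `n * p`.
#'
#' @param annotation A [cell_annotation()].
#' @param rule A [classification_rule()].
#' @param fp_rate False positives per marked object, from
#'   [false_positive_rate()].
#' @param miss_prob Orientation miss probability, from
#'   [orientation_miss_probability()]; must be `< 1`.
#' @param miss_mode `"inversion"` or `"direct"` (see Details).
#' @return A `virion_count`: list with `n_virions`, `n_marks_total`,
#'   `uncertainty` and its two `components`.
#' @export
count_with_uncertainty <- function(annotation, rule = classification_rule(),
                                   fp_rate = 0, miss_prob = 0,
                                   miss_mode = c("inversion", "direct")) {
  miss_mode <- match.arg(miss_mode)
  stopifnot(inherits(annotation, "cell_annotation"),
            fp_rate >= 0, fp_rate <= 1, miss_prob >= 0)
  if (miss_prob >= 1) stop("`miss_prob` must be < 1")
  lab <- classify_marks(annotation$marks, rule)
  n <- sum(lab == "virion")
  n_tot <- length(lab)
  fp <- fp_rate * n_tot
  miss <- switch(miss_mode,
                 inversion = n * miss_prob / (1 - miss_prob),
                 direct = n * miss_prob)
  structure(list(cell_id = annotation$cell_id, hpi = annotation$hpi,
                 n_virions = n, n_marks_total = n_tot,
                 uncertainty = fp + miss,
                 components = c(false_positive_estimate = fp,
                                orientation_miss_estimate = miss),
                 approximate = annotation$approximate),
            class = "virion_count")
}

#' @export
print.virion_count <- function(x, ...) {
  cat(sprintf("%s (%g hpi): %d virions of %d marks, +/- %.1f (FP %.1f, orientation %.1f)%s\n",
              x$cell_id, x$hpi, x$n_virions, x$n_marks_total, x$uncertainty,
              x$components[["false_positive_estimate"]],
              x$components[["orientation_miss_estimate"]],
              if (x$approximate) " [approximate]" else ""))
  invisible(x)
}

#' Summarise virion counts by infection time
#'
#' Plain arithmetic mean of per-cell counts and uncertainties at each
#' infection time, ordered by increasing hpi, with the approximate flag
#' propagated if any contributing cell was flagged.
#'
#' @param counts List of `virion_count` objects (see
#'   [count_with_uncertainty()]).
#' @return Data frame with columns `hpi`, `n_cells`, `mean_virions`,
#'   `mean_uncertainty`, `approximate`.
#' @export
cohort_summary <- function(counts) {
  stopifnot(length(counts) >= 1,
            all(vapply(counts, inherits, TRUE, "virion_count")))
  df <- data.frame(hpi = vapply(counts, `[[`, 0, "hpi"),
                   n = vapply(counts, `[[`, 0, "n_virions"),
                   u = vapply(counts, `[[`, 0, "uncertainty"),
                   approx = vapply(counts, `[[`, TRUE, "approximate"))
  out <- do.call(rbind, lapply(split(df, df$hpi), function(g) {
    data.frame(hpi = g$hpi[1], n_cells = nrow(g),
               mean_virions = mean(g$n), mean_uncertainty = mean(g$u),
               approximate = any(g$approx))
  }))
  out <- out[order(out$hpi), , drop = FALSE]
  rownames(out) <- NULL
  out
}
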