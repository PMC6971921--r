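# Per-subject summaries, descriptive group tables, percent differences,
# and Mann-Whitney U comparison of feature points and harmonics.

#' Summarize one subject
#'
#' Collapses a subject's profiles into spine-averaged scalars (equal-weight
#' mean over the 1 mm slices) plus totals for volumes and surface areas,
#' and attaches per-station feature points and harmonic spectra. Geometry
#' may be present while flow is excluded (e.g. near-zero flow): the
#' hydrodynamic fields are then `NA` and the exclusion reason is recorded.
#'
#' @param id,group Subject identifier and group label.
#' @param geometry A [geometry_profile()] (required).
#' @param hydro Optional list with elements `re` ([reynolds_profile()]
#'   output), `alpha` ([womersley_profile()]), `vel`
#'   ([velocity_profiles()]), `flow` (`spatiotemporal_flow`) and `pwv`
#'   (`pwv_fit`).
#' @param features Optional data.frame of per-station feature points
#'   (columns `station`, `q_sys`, `t_sys`, `q_dia`, `t_dia`, `u_sys`,
#'   `u_dia`).
#' @param spectra Optional data.frame of per-station harmonics (columns
#'   `station`, `harmonic`, `magnitude`, `phase`).
#' @param exclusions Character vector of machine-readable exclusion
#'   reasons (e.g. `"near-zero flow"`).
#' @return An object of class `subject_summary`: `id`, `group`, `scalars`
#'   (named numeric), `features`, `spectra`, `exclusions`.
#' @export
summarize_subject <- function(id, group, geometry, hydro = NULL,
                              features = NULL, spectra = NULL,
                              exclusions = character()) {
  stopifnot(inherits(geometry, "geometry_profile"))
  sl <- geometry$slices
  scalars <- c(
    p_c = mean(sl$p_c), p_d = mean(sl$p_d), p_cs = mean(sl$p_cs),
    a_c = mean(sl$a_c), a_d = mean(sl$a_d), a_cs = mean(sl$a_cs),
    v_c = geometry$v_c, v_d = geometry$v_d, v_cs = geometry$v_cs,
    sa_c = geometry$sa_c, sa_d = geometry$sa_d, sa_cs = geometry$sa_cs,
    d_h = mean(sl$d_h, na.rm = TRUE)
  )
  hyd <- c(re = NA_real_, alpha = NA_real_, u_sys = NA_real_,
           u_dia = NA_real_, q_sys = NA_real_, q_dia = NA_real_,
           pwv = NA_real_)
  if (!is.null(hydro)) {
    hyd["re"] <- mean(hydro$re$re)
    hyd["alpha"] <- mean(hydro$alpha$alpha)
    hyd["u_sys"] <- mean(hydro$vel$u_sys)
    hyd["u_dia"] <- mean(hydro$vel$u_dia)
    hyd["q_sys"] <- mean(hydro$flow$q_sys)
    hyd["q_dia"] <- mean(hydro$flow$q_dia)
    hyd["pwv"] <- if (hydro$pwv$infinite) NA_real_ else hydro$pwv$pwv_cm_s
  }
  structure(
    list(id = id, group = group, scalars = c(scalars, hyd),
         features = features, spectra = spectra,
         exclusions = exclusions),
    class = "subject_summary"
  )
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test with the
#' `U = min(U_A, U_B)` reporting convention. The p-value is exact (null
#' enumeration) for tie-free samples of workable size and otherwise uses
#' the normal approximation with tie and continuity correction.
#'
#' @param a,b Numeric samples (nonempty).
#' @return A list: `u`, `p`, `method` (`"exact"` or `"approximate"`).
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) * length(b) <= 1e6
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  u_a <- unname(wt$statistic)
  u <- min(u_a, length(a) * length(b) - u_a)
  list(u = u, p = wt$p.value,
       method = if (exact) "exact" else "approximate")
}

#' Percent difference relative to a reference mean
#'
#' `100 * (reference - comparison) / reference`. The unrounded value is
#' returned; report text rounds to the nearest integer percent.
#'
#' @param reference,comparison Group means (reference nonzero).
#' @return Unrounded percent difference.
#' @export
percent_difference <- function(reference, comparison) {
  if (any(reference == 0)) stop("zero reference mean")
  100 * (reference - comparison) / reference
}

#' Compare two groups of subject summaries
#'
#' Builds (i) a descriptive table of every scalar parameter with per-group
#' mean +/- sample SD and the percent difference of the comparison group
#' relative to the reference group; (ii) Mann-Whitney U tests of the
#' per-station feature points (`q_sys`, `t_sys`, `q_dia`, `t_dia`); and
#' (iii) Mann-Whitney U tests of each harmonic magnitude per station.
#' Subjects excluded from flow analyses contribute to the geometric rows
#' only. P-values are uncorrected by default (`p_adjust = "none"`), with
#' Benjamini-Hochberg available; the significance flag uses `alpha`.
#'
#' @param summaries List of [summarize_subject()] objects.
#' @param reference Reference group label; defaults to the first group
#'   encountered.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return An object of class `group_comparison`: `params`,
#'   `feature_tests`, `harmonic_tests` (data.frames), `groups`, `n`,
#'   `alpha`, `p_adjust`.
#' @export
compare_groups <- function(summaries, reference = NULL, alpha = 0.05,
                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  groups <- unique(vapply(summaries, `[[`, "", "group"))
  if (length(groups) != 2) stop("exactly two groups required")
  if (is.null(reference)) reference <- groups[1]
  other <- setdiff(groups, reference)
  by_group <- split(summaries, vapply(summaries, `[[`, "", "group"))

  scal <- function(ss) do.call(rbind, lapply(ss, `[[`, "scalars"))
  A <- scal(by_group[[reference]])
  B <- scal(by_group[[other]])
  params <- data.frame(
    parameter = colnames(A),
    ref_mean = colMeans(A, na.rm = TRUE),
    ref_sd = apply(A, 2, sd, na.rm = TRUE),
    cmp_mean = colMeans(B, na.rm = TRUE),
    cmp_sd = apply(B, 2, sd, na.rm = TRUE),
    row.names = NULL
  )
  pd <- rep(NA_real_, nrow(params))
  ok <- !is.na(params$ref_mean) & !is.na(params$cmp_mean) &
    params$ref_mean != 0
  pd[ok] <- percent_difference(params$ref_mean[ok], params$cmp_mean[ok])
  params$percent_difference <- pd

  feature_tests <- .test_long(summaries, reference, other, "features",
                              c("q_sys", "t_sys", "q_dia", "t_dia"))
  harmonic_tests <- .test_harmonics(summaries, reference, other)
  for (nm in c("feature_tests", "harmonic_tests")) {
    tab <- get(nm)
    if (nrow(tab)) {
      tab$p_adjusted <- if (p_adjust == "BH")
        stats::p.adjust(tab$p, "BH") else tab$p
      tab$significant <- tab$p_adjusted < alpha
    }
    assign(nm, tab)
  }

  structure(
    list(params = params, feature_tests = feature_tests,
         harmonic_tests = harmonic_tests,
         groups = c(reference = reference, comparison = other),
         n = vapply(by_group, length, 0L),
         alpha = alpha, p_adjust = p_adjust),
    class = "group_comparison"
  )
}

.flow_included <- function(s) length(s$exclusions) == 0

.test_long <- function(summaries, ref, other, what, vars) {
  tabs <- lapply(summaries, function(s) {
    if (is.null(s[[what]]) || !.flow_included(s)) return(NULL)
    cbind(s[[what]], group = s$group)
  })
  tab <- do.call(rbind, tabs)
  out <- list()
  if (is.null(tab)) return(data.frame())
  for (st in unique(tab$station)) {
    for (v in vars) {
      a <- tab[[v]][tab$station == st & tab$group == ref]
      b <- tab[[v]][tab$station == st & tab$group == other]
      if (sum(!is.na(a)) == 0 || sum(!is.na(b)) == 0) next
      mw <- mann_whitney_u(a, b)
      out[[length(out) + 1L]] <- data.frame(
        station = st, variable = v,
        ref_mean = mean(a, na.rm = TRUE), cmp_mean = mean(b, na.rm = TRUE),
        u = mw$u, p = mw$p, method = mw$method)
    }
  }
  if (length(out) == 0) return(data.frame())
  do.call(rbind, out)
}

.test_harmonics <- function(summaries, ref, other) {
  tabs <- lapply(summaries, function(s) {
    if (is.null(s$spectra) || !.flow_included(s)) return(NULL)
    cbind(s$spectra, group = s$group)
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab)) return(data.frame())
  out <- list()
  for (st in unique(tab$station)) {
    for (h in sort(unique(tab$harmonic))) {
      sel <- tab$station == st & tab$harmonic == h
      a <- tab$magnitude[sel & tab$group == ref]
      b <- tab$magnitude[sel & tab$group == other]
      if (length(a) == 0 || length(b) == 0) next
      mw <- mann_whitney_u(a, b)
      out[[length(out) + 1L]] <- data.frame(
        station = st, harmonic = h,
        ref_mean = mean(a), cmp_mean = mean(b),
        u = mw$u, p = mw$p, method = mw$method)
    }
  }
  if (length(out) == 0) return(data.frame())
  do.call(rbind, out)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: %s (n=%d, reference) vs %s (n=%d)\n",
              x$groups["reference"], x$n[[x$groups["reference"]]],
              x$groups["comparison"], x$n[[x$groups["comparison"]]]))
  p <- x$params
  p$percent_difference <- round(p$percent_difference)
  print(p, digits = 4)
  nsig <- function(t) if (nrow(t)) sum(t$significant) else 0L
  cat(sprintf("Feature-point tests: %d significant of %d (uncorrected p < %.2f)\n",
              nsig(x$feature_tests), nrow(x$feature_tests), x$alpha))
  cat(sprintf("Harmonic tests: %d significant of %d\n",
              nsig(x$harmonic_tests), nrow(x$harmonic_tests)))
  invisible(x)
}

#' Published cohort summary values for the worked examples
#'
#' Published spine-averaged group means for a healthy control cohort and
#' an ALS cohort: geometric rows
#' (perimeters cm, areas cm^2, volumes cm^3, surface areas cm^2, hydraulic
#' diameter cm) and hydrodynamic rows (Reynolds and Womersley numbers,
#' velocities cm/s, flows cm^3/s, PWV cm/s). Used as inputs to the
#' percent-difference worked examples; they are reported values, not
#' outputs of this package.
#'
#' @return data.frame with columns `parameter`, `control`, `als`.
#' @export
reference_cohort_means <- function() {
  data.frame(
    parameter = c("p_c", "p_d", "p_cs", "a_c", "a_d", "a_cs",
                  "v_c", "v_d", "v_cs", "sa_c", "sa_d", "sa_cs",
                  "d_h", "re", "alpha", "u_sys", "u_dia",
                  "q_sys", "q_dia", "pwv"),
    control = c(1.87, 5.66, 7.53, 0.35, 2.13, 1.78,
                20.99, 129.19, 108.20, 113.52, 344.12, 457.64,
                0.96, 194.74, 12.71, -1.30, 0.76, -1.88, 1.06, 347.41),
    als = c(1.88, 5.25, 7.13, 0.35, 1.89, 1.53,
            22.53, 119.83, 97.30, 119.37, 333.54, 452.91,
            0.89, 209.37, 11.92, -1.29, 0.70, -1.58, 0.83, 473.19)
  )
}
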