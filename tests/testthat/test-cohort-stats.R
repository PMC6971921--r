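# Subject summaries, Mann-Whitney U, percent differences, group tables.

# Independent oracle: exact two-sided Mann-Whitney p by enumerating every
# labeling of the pooled sample (tie-free inputs).
enumerate_mwu_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  u_of <- function(idx) {
    ra <- rank(pool)[idx]
    sum(ra) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  us <- apply(utils::combn(n, na), 2, u_of)
  mu <- na * (length(b)) / 2
  # two-sided: as extreme or more extreme in either direction
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

test_that("exact U test matches full enumeration on small samples", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$method, "exact")
  expect_equal(res$p, enumerate_mwu_p(c(1, 2, 3), c(4, 5, 6)))  # 0.1
  expect_equal(res$p, 0.1)

  res1 <- mann_whitney_u(1, 2)
  expect_equal(res1$u, 0)
  expect_equal(res1$p, 1.0)  # both labelings equally extreme

  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(sample(2:5, 1)); b <- rnorm(sample(2:5, 1))
    expect_equal(mann_whitney_u(a, b)$p, enumerate_mwu_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("identical samples give p = 1 and ties fall back to the approximation", {
  res <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p, 1.0)
  expect_equal(res$method, "approximate")
})

test_that("exact and approximate p agree closely on tie-free samples", {
  set.seed(31)
  for (i in 1:50) {
    a <- rnorm(sample(4:8, 1)); b <- rnorm(sample(4:8, 1))
    pe <- mann_whitney_u(a, b)$p
    pa <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                       correct = TRUE)$p.value)
    expect_lt(abs(pe - pa), 0.04)
  }
})

test_that("type-I error of the U test sits at the nominal 5% level", {
  set.seed(101)
  n_pairs <- 1000
  rejections <- 0
  for (i in seq_len(n_pairs)) {
    a <- rnorm(10); b <- rnorm(8)  # null: same distribution
    if (mann_whitney_u(a, b)$p < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_pairs
  # exact test at discrete alpha: achievable level <= 0.05; 3 MC sigmas ~ 0.021
  expect_lt(abs(rate - 0.05), 0.025)
})

test_that("percent differences reproduce the published worked values", {
  expect_equal(round(percent_difference(1.78, 1.53)), 14)
  expect_equal(round(percent_difference(108.2, 97.3)), 10)
  expect_equal(percent_difference(3, 3), 0)
  expect_error(percent_difference(0, 1), "zero reference")
})

test_that("subject summaries average slices and honor flow exclusion", {
  geom <- constant_geometry(0:100, a_cs = 1.5, d_h = 0.8, a_c = 0.5)
  s <- summarize_subject("S1", "g", geom)
  expect_equal(unname(s$scalars["a_cs"]), 1.5)
  expect_equal(unname(s$scalars["a_c"]), 0.5)
  expect_equal(unname(s$scalars["v_cs"]), 1.5 * 101 * 0.1)
  expect_true(is.na(s$scalars["pwv"]))
  s2 <- summarize_subject("S2", "g", geom, exclusions = "near-zero flow")
  expect_true(is.na(s2$scalars["q_sys"]))
  expect_identical(s2$exclusions, "near-zero flow")
})

make_summary <- function(id, group, a_cs = 1.5, q_sys = -2, t_sys = 0.2,
                         h_mags = rep(0.5, 7)) {
  geom <- constant_geometry(0:10, a_cs = a_cs)
  feats <- data.frame(station = c("FM", "C2-C3"),
                      q_sys = q_sys, t_sys = t_sys,
                      q_dia = -q_sys / 2, t_dia = 0.7,
                      u_sys = q_sys / a_cs, u_dia = -q_sys / (2 * a_cs))
  spectra <- do.call(rbind, lapply(c("FM", "C2-C3"), function(st)
    data.frame(station = st, harmonic = 1:7, magnitude = h_mags,
               phase = 0)))
  summarize_subject(id, group, geom, features = feats, spectra = spectra)
}

test_that("identical groups compare with zero percent difference and p = 1", {
  set.seed(5)
  ss <- c(lapply(1:4, function(i) make_summary(paste0("a", i), "a",
                                               q_sys = -2 + 0.1 * i)),
          lapply(1:4, function(i) make_summary(paste0("b", i), "b",
                                               q_sys = -2 + 0.1 * i)))
  cmp <- compare_groups(ss)
  expect_true(all(abs(cmp$params$percent_difference) < 1e-9,
                  na.rm = TRUE))
  expect_true(all(cmp$feature_tests$p[cmp$feature_tests$variable == "q_sys"] == 1))
  expect_false(any(cmp$feature_tests$significant[
    cmp$feature_tests$variable == "q_sys"]))
})

test_that("a contrast confined to harmonic 6 is flagged only at harmonic 6", {
  # within-group spread is identical across groups (same multiset) at every
  # harmonic except the 6th, which is cleanly separated in group b
  mags <- function(i, h6) {
    base <- c(1, 0.6, 0.3, 0.2, 0.12, 0.05, 0.03) * (1 + 0.02 * i)
    base[6] <- 0.05 * (1 + 0.02 * i) + h6
    base
  }
  ss <- c(lapply(1:8, function(i) make_summary(paste0("a", i), "a",
                                               h_mags = mags(i, 0))),
          lapply(1:8, function(i) make_summary(paste0("b", i), "b",
                                               h_mags = mags(i, 0.3))))
  cmp <- compare_groups(ss)
  ht <- cmp$harmonic_tests
  expect_true(all(ht$significant[ht$harmonic == 6]))
  expect_false(any(ht$significant[ht$harmonic != 6]))
  expect_equal(min(ht$p[ht$harmonic == 6]), 2 / choose(16, 8),
               tolerance = 1e-12)
})

test_that("excluded subjects contribute geometry but not flow comparisons", {
  ss <- c(lapply(1:3, function(i) make_summary(paste0("a", i), "a",
                                               q_sys = -2 - 0.01 * i)),
          lapply(1:3, function(i) make_summary(paste0("b", i), "b",
                                               q_sys = -1 - 0.01 * i)),
          list(summarize_subject("b4", "b", constant_geometry(0:10),
                                 exclusions = "near-zero flow")))
  cmp <- compare_groups(ss)
  expect_equal(unname(cmp$n["b"]), 4L)        # geometry row counts all
  ft <- cmp$feature_tests
  # U computed from 3 vs 3 subjects: min-U convention bounded by 9
  expect_true(all(ft$u <= 9))
})
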