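test_that("count_pairs follows n(n-1)/2 and matches enumeration", {
  expect_identical(count_pairs(36), 630)
  expect_identical(count_pairs(3), 3)
  for (n in c(2, 5, 10, 17)) {
    expect_identical(count_pairs(n), nrow(t(utils::combn(n, 2))) * 1)
  }
  expect_error(count_pairs(1), ">= 2")
})

test_that("concordance labels and tau-b match hand-worked examples", {
  r <- concordance_analysis(c(1, 2, 3), c(10, 20, 30))
  expect_identical(c(r$n_concordant, r$n_discordant, r$n_tied), c(3L, 0L, 0L))
  expect_equal(r$tau_b, 1)

  # minors (3,1,2) vs majors (2,3,1): only the A-C pair is concordant
  r2 <- concordance_analysis(c(3, 1, 2), c(2, 3, 1), blend_ids = c("A", "B", "C"))
  expect_identical(c(r2$n_concordant, r2$n_discordant), c(1L, 2L))
  expect_equal(r2$tau_b, -1 / 3)
  conc <- r2$pairs[r2$pairs$label == "concordant", ]
  expect_identical(unlist(conc[, c("blend_i", "blend_j")], use.names = FALSE),
                   c("A", "C"))
})

test_that("pair accounting and the closed form hold on random vectors", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    if (i %% 5 == 0) {  # inject ties
      x <- round(x, 1); y <- round(y, 1)
    }
    r <- concordance_analysis(x, y)
    expect_identical(r$n_concordant + r$n_discordant + r$n_tied,
                     as.integer(count_pairs(n)))
    expect_identical(r$pairs$label, brute_pairs(x, y))
    # independent oracle: tie-corrected tau and normal-approximation p
    ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                           exact = FALSE))
    expect_equal(r$tau_b, unname(ct$estimate), tolerance = 1e-12)
    if (n > 10) expect_equal(r$p_value, ct$p.value, tolerance = 1e-6)
  }
})

test_that("constant input flags tau as undefined", {
  r <- concordance_analysis(rep(1, 5), rnorm(5))
  expect_true(r$constant_input)
  expect_true(is.na(r$tau_b))
  expect_identical(r$n_pairs, 10L)   # pairs still labelled (all tied in x)
})

test_that("caste comparison finds nothing under an exact null", {
  m <- make_matrix(8, 5, function(b, cc, n) seq_len(n) / 10)  # identical sets
  cmp <- compare_castes(m)
  expect_false(any(cmp$significant))
  expect_true(all(cmp$p_value == 1))
})

test_that("Welch t negates and p is preserved under caste-label swap", {
  set.seed(1)
  m <- make_matrix(6, 8, function(b, cc, n) rnorm(n, if (cc == "minor") 0.2 else 0))
  swapped <- m
  swapped$caste <- ifelse(m$caste == "minor", "major", "minor")
  a <- compare_castes(m); b <- compare_castes(swapped)
  expect_equal(a$welch_t, -b$welch_t)
  expect_equal(a$p_value, b$p_value)
})

test_that("a planted 5-sigma caste shift is recovered with high power", {
  # 12 shifted blends among 36, shift = 5 x noise sd, n = 25 per caste
  shifted <- 1:12
  hits <- 0L; total <- 0L; extras <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    m <- make_matrix(36, 25, function(b, cc, n) {
      mu <- if (cc == "minor" && b %in% shifted) 0.5 else 0
      rnorm(n, mu, 0.1)
    })
    cmp <- compare_castes(m)
    hits <- hits + sum(cmp$significant[shifted])
    extras <- extras + sum(cmp$significant[-shifted])
    total <- total + length(shifted)
  }
  expect_gte(hits / total, 0.95)
  expect_lt(extras / (100 * 24), 0.1)   # false positives controlled
})

test_that("blends with too few replicates are excluded with a warning", {
  m <- make_matrix(3, 5, function(b, cc, n) rnorm(n))
  m <- m[!(m$blend_id == 2 & m$caste == "major" &
             m$preparation_id != "major_1"), ]
  expect_warning(cmp <- compare_castes(m), "excluding blend")
  expect_identical(cmp$blend_id, c(1L, 3L))
})

test_that("solvent classification assigns the four sign/significance categories", {
  set.seed(10)
  m <- make_matrix(4, 25, function(b, cc, n) {
    base <- c(0.5, 0.02, -0.02, -0.5)[b]
    base + rnorm(n, 0, 0.1)
  })
  cls <- classify_vs_solvent(m)
  per_blend <- split(cls$classification$category, cls$classification$blend_id)
  expect_true(all(per_blend[["1"]] == "sig_above"))
  expect_true(all(per_blend[["4"]] == "sig_below"))
  expect_true(all(per_blend[["2"]] %in% c("ns_above", "ns_below")))
  counts <- cls$counts
  expect_identical(sum(counts$n[counts$caste == "minor"]), 4L)
})

test_that("all-zero replicates classify as non-significant, zero variance flagged", {
  m <- make_matrix(3, 5, function(b, cc, n) rep(0, n))
  cls <- classify_vs_solvent(m)
  expect_true(all(cls$classification$category == "ns_above"))
  expect_true(all(cls$classification$degenerate))
  expect_true(all(is.na(cls$classification$q_value)))
})

test_that("sub-solvent Fisher test matches exhaustive hypergeometric enumeration", {
  balanced <- tibble::tibble(blend_id = 1:36,
                             mean_mV = rep(c(-1, 1), each = 18))
  r <- sub_solvent_fisher(balanced, balanced)
  expect_equal(r$p_value, 1)

  # 30/6 sub-solvent vs 10/26: compare with brute-force tail sum
  minor <- tibble::tibble(blend_id = 1:36, mean_mV = c(rep(-1, 30), rep(1, 6)))
  major <- tibble::tibble(blend_id = 1:36, mean_mV = c(rep(-1, 10), rep(1, 26)))
  r2 <- sub_solvent_fisher(minor, major)
  expect_identical(unname(r2$table[1, ]), c(30L, 6L))
  expect_equal(r2$p_value, brute_fisher_p(r2$table), tolerance = 1e-9)
  expect_equal(r2$p_value, stats::fisher.test(r2$table)$p.value)

  # zero margin: degenerate, p = 1
  all_sub <- tibble::tibble(blend_id = 1:6, mean_mV = rep(-1, 6))
  r3 <- sub_solvent_fisher(all_sub, all_sub)
  expect_true(r3$degenerate)
  expect_equal(r3$p_value, 1)

  expect_error(sub_solvent_fisher(minor, major[1:10, ]), "same blend set")
})

test_that("per-class pair sets have size k(n-k) + C(k,2) and proportions follow labels", {
  panel <- synthetic_blend_panel()
  x <- seq_len(36); y <- seq_len(36)
  conc <- concordance_analysis(x, y, blend_ids = 1:36)
  pcd <- per_class_discordance(conc$pairs, panel)
  k <- table(unique(panel[, c("blend_id", "class")])$class)
  for (i in seq_len(nrow(pcd))) {
    kk <- as.integer(k[[pcd$class[i]]])
    expect_identical(pcd$n_pairs[i], as.integer(kk * (36 - kk) + kk * (kk - 1) / 2))
  }
  # single-blend class denominator is n - 1 = 35
  expect_identical(pcd$n_pairs[pcd$class == "alkane"], 35L)
  # identical rankings: zero discordance everywhere
  expect_true(all(pcd$proportion == 0))
  expect_error(
    per_class_discordance(conc$pairs, panel[panel$class != "alkane", ]),
    "without a class")
})
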