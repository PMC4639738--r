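sim_design <- function(seed, n_per_group = 10, groups = 4) {
  withr::with_seed(seed, {
    n <- n_per_group * groups
    tibble::tibble(
      random_group = rep(paste0("G", seq_len(groups)), each = n_per_group),
      group_id = rep(paste0("G", seq_len(groups)), each = n_per_group),
      sex = sample(c("female", "male"), n, replace = TRUE),
      age_class = sample(c("mature", "old"), n, replace = TRUE),
      deprivation_class = sample(c("ND", "EMD", "ELD", "LLD"), n,
                                 replace = TRUE))
  })
}

test_that("AICc follows the small-sample correction formula", {
  expect_equal(aicc_value(-10, k = 3, n = 20), 27.5)
  expect_equal(aicc_value(-10, k = 0, n = 20), 20)
  expect_equal(aicc_value(-5, k = 2, n = 1e3) - (10 + 4), 12 / 997)
  expect_lt(aicc_value(-5, k = 2, n = 1e6) - (10 + 4), 2e-5)
  expect_error(aicc_value(-10, k = 5, n = 6), "AICc undefined")
})

test_that("model specs enforce marginality", {
  expect_error(model_spec("y", c("sex", "sex:deprivation_class")),
               "marginality")
  expect_silent(model_spec("y", c("sex", "deprivation_class",
                                  "sex:deprivation_class")))
  expect_error(model_spec("y", "weekday"), "unknown fixed term")
})

test_that("a noiseless linear response is recovered exactly", {
  d <- sim_design(1)
  d$y <- 3 + 2 * (d$sex == "male") - 1.5 * (d$deprivation_class == "ELD")
  fit <- fit_lmm(d, model_spec("y", c("sex", "deprivation_class")))
  expect_lt(fit$sigma, 1e-6)
  mm <- stats::model.matrix(fit$model)
  pred <- as.vector(mm %*% fit$coefficients)
  expect_equal(pred, d$y, tolerance = 1e-8)
  expect_true(all(fit$terms$df2 == nrow(d) - length(fit$coefficients)))
})

test_that("a constant response yields zero slopes and F about zero", {
  d <- sim_design(2)
  d$y <- 7
  fit <- fit_lmm(d, model_spec("y", c("sex", "deprivation_class")))
  expect_equal(unname(fit$coefficients[-1]), rep(0, 4))
  expect_true(all(fit$terms$F < 1e-8))
})

test_that("fit_lmm validates its inputs", {
  d <- sim_design(3)
  d$y <- rnorm(nrow(d))
  expect_error(fit_lmm(d, model_spec("z")), "response column")
  d1 <- d[d$random_group == "G1", ]
  d1$y <- rnorm(nrow(d1))
  expect_error(fit_lmm(d1, model_spec("y")), "at least 2 groups")
  d$y[1] <- NA
  expect_error(fit_lmm(d, model_spec("y")), "missing values")
})

test_that("a strong class effect is detected across seeds", {
  hits <- sapply(1:30, function(seed) {
    d <- sim_design(seed)
    withr::with_seed(seed + 1000, {
      d$y <- 2 * (d$deprivation_class == "ELD") + rnorm(nrow(d))
    })
    fit <- fit_lmm(d, model_spec("y", "deprivation_class"))
    fit$terms$p[fit$terms$term == "deprivation_class"] < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("backward selection respects marginality and records a ledger", {
  d <- sim_design(5)
  withr::with_seed(99, d$y <- 2 * (d$deprivation_class == "ELD") +
                     rnorm(nrow(d)))
  sel <- backward_select(d, model_spec("y"))
  expect_true(all(is.finite(sel$ledger$aicc)))
  # every candidate model recorded at every step obeys marginality
  for (m in sel$ledger$model) {
    terms <- strsplit(m, " \\+ ")[[1]]
    if (m != "1") expect_silent(scansoc:::check_marginality(terms))
  }
  expect_true(methods::is(sel$best_reml, "lmerMod"))
  # drop order tie-break: interactions are offered before main effects
  expect_equal(scansoc:::term_order(c("age_class", "sex:deprivation_class", "sex")),
               c("sex:deprivation_class", "age_class", "sex"))
})

test_that("when the full model already has the lowest AICc it is kept", {
  # make every term matter so that no drop can improve AICc
  d <- sim_design(6)
  withr::with_seed(7, {
    d$y <- 3 * (d$sex == "male") + 3 * (d$age_class == "old") +
      3 * (d$deprivation_class == "ELD") +
      3 * (d$sex == "male" & d$deprivation_class == "LLD") +
      rnorm(nrow(d), sd = 0.4)
  })
  sel <- backward_select(d, model_spec("y"))
  expect_setequal(sel$best$spec$fixed_terms,
                  c("age_class", "sex", "deprivation_class",
                    "sex:deprivation_class"))
  expect_equal(sum(sel$ledger$chosen), 1)  # only the full model chosen
})

test_that("Mann-Whitney U follows the min convention and exact/approx rules", {
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$method, "exact")
  same <- mann_whitney_u(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(same$U, 4 * 4 / 2)
  expect_equal(same$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")

  # label-antisymmetry: swapping samples leaves U (min convention) and p
  withr::with_seed(21, {
    for (i in 1:10) {
      a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
      m1 <- mann_whitney_u(a, b); m2 <- mann_whitney_u(b, a)
      expect_equal(m1$U, m2$U)
      expect_equal(m1$p, m2$p)
    }
  })

  # tie-corrected normal branch agrees with the classical implementation
  withr::with_seed(33, {
    for (i in 1:10) {
      a <- sample(1:5, 12, replace = TRUE)
      b <- sample(1:5, 40, replace = TRUE)  # n_a * n_b > 400 -> approx
      mine <- mann_whitney_u(a, b)
      expect_equal(mine$method, "normal_tie_corrected")
      ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
      expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("Holm adjustment matches the step-down rule and its properties", {
  expect_equal(holm_adjust(0.04), 0.04)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  withr::with_seed(8, {
    for (i in 1:20) {
      p <- runif(sample(1:8, 1))
      adj <- holm_adjust(p)
      expect_equal(adj, hand_holm(p))
      # permutation equivariance
      perm <- sample(length(p))
      expect_equal(holm_adjust(p[perm]), adj[perm])
      # dominates Bonferroni from below
      expect_true(all(adj <= pmin(1, length(p) * p) + 1e-15))
      expect_true(all(adj >= p))
    }
  })
})

posthoc_fixture <- function(seed = 4, with_lmd = FALSE) {
  withr::with_seed(seed, {
    classes <- c(rep("ELD", 10), rep("LLD", 8), rep("EMD", 7), rep("ND", 16))
    if (with_lmd) classes <- c(classes, "LMD", "LMD")
    n <- length(classes)
    tibble::tibble(
      id = paste0("i", seq_len(n)),
      behaviour = "grooming", period_id = "P1",
      deprivation_class = classes,
      sex = rep(c("female", "male"), length.out = n),
      strength_centrality = rnorm(n, 5),
      y2 = runif(n, 0.1, 1), dy2 = runif(n), defined = TRUE)
  })
}

test_that("posthoc families follow the retained terms", {
  tab <- posthoc_fixture()
  ph <- posthoc_pairwise(tab, "strength_centrality")
  expect_equal(nrow(ph), choose(4, 2))
  expect_true(all(ph$family == "deprivation_class"))

  ph2 <- posthoc_pairwise(tab, "strength_centrality",
                          retained_terms = c("sex", "deprivation_class",
                                             "sex:deprivation_class"))
  expect_true(any(ph2$family == "sex"))
  expect_true(any(ph2$family == "sex_by_class"))
  # Holm within family: adjusted never below raw, monotone in order
  for (fam in unique(ph2$family)) {
    sub <- ph2[ph2$family == fam, ]
    expect_true(all(sub$p_holm >= sub$p_raw - 1e-15))
    expect_equal(sub$p_holm, hand_holm(sub$p_raw))
  }
})

test_that("small classes are excluded from every posthoc family", {
  tab <- posthoc_fixture(with_lmd = TRUE)
  ph <- posthoc_pairwise(tab, "strength_centrality", min_class_n = 3,
                         retained_terms = c("sex", "deprivation_class",
                                            "sex:deprivation_class"))
  expect_false(any(ph$level_a == "LMD" | ph$level_b == "LMD"))
  # with a single eligible class the table is empty and a note is logged
  tiny <- tab[tab$deprivation_class %in% c("ND", "LMD"), ]
  expect_message(out <- posthoc_pairwise(tiny, "strength_centrality",
                                         min_class_n = 3),
                 "fewer than 2 eligible")
  expect_equal(nrow(out), 0)
})

test_that("undefined disparity rows are excluded listwise from posthocs", {
  tab <- posthoc_fixture()
  tab$defined[tab$deprivation_class == "ELD"][1:8] <- FALSE
  tab$dy2[!tab$defined] <- NA
  ph <- posthoc_pairwise(tab, "dy2")
  eld <- ph[ph$level_a == "ELD" | ph$level_b == "ELD", ]
  # 2 defined ELD rows < min_class_n -> ELD drops out entirely
  expect_equal(nrow(eld), 0)
  expect_equal(nrow(ph), choose(3, 2))
})
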