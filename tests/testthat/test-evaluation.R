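test_that("residue metrics match hand arithmetic on a known confusion", {
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.7, -0.2, 0.6, -0.1, -0.3, -0.5, -0.6, -0.8)
  m <- residue_metrics(labels, scores, threshold = 0)
  # TP=3 FN=1 TN=5 FP=1 by inspection
  expect_equal(m$tp, 3); expect_equal(m$fn, 1)
  expect_equal(m$tn, 5); expect_equal(m$fp, 1)
  expect_equal(m$sn, 0.75)
  expect_equal(m$sp, 5 / 6)
  expect_equal(m$acc, 0.8)
  expect_equal(m$f, 0.75)
})

test_that("metric identities hold over random confusion tables", {
  withr::with_seed(41, {
    for (rep in seq_len(1000)) {
      counts <- sample(0:30, 4, replace = TRUE)
      tp <- counts[1]; fp <- counts[2]; tn <- counts[3]; fn <- counts[4]
      if (sum(counts) == 0) next
      labels <- rep(c(1, 1, 0, 0), counts[c(1, 4, 3, 2)])
      scores <- rep(c(1, -1, -1, 1), counts[c(1, 4, 3, 2)])
      m <- residue_metrics(labels, scores, threshold = 0)
      expect_identical(c(m$tp, m$fp, m$tn, m$fn), c(tp, fp, tn, fn))
      tol <- 1e-12
      if (tp + fn > 0) expect_equal(m$sn, tp / (tp + fn), tolerance = tol)
      else expect_true(is.na(m$sn))
      if (tn + fp > 0) expect_equal(m$sp, tn / (tn + fp), tolerance = tol)
      else expect_true(is.na(m$sp))
      expect_equal(m$acc, (tp + tn) / sum(counts), tolerance = tol)
      if (2 * tp + fn + fp > 0) {
        expect_equal(m$f, 2 * tp / (2 * tp + fn + fp), tolerance = tol)
      } else {
        expect_true(is.na(m$f))
      }
    }
  })
})

test_that("midrank AUC equals the brute-force all-pairs oracle", {
  brute_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n)))
  }
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(10:200, 1)
      y <- rbinom(n, 1, 0.3)
      if (length(unique(y)) < 2) next
      s <- round(rnorm(n), 1)  # coarse scores force ties
      expect_equal(auc_midrank(y, s), brute_auc(y, s))
    }
  })
  expect_equal(auc_midrank(c(0, 0, 1, 1), c(-1, -2, 3, 4)), 1)
  expect_true(is.na(auc_midrank(c(1, 1), c(0.2, 0.3))))
})

test_that("epitope matching follows the strict 30% coverage rule", {
  obs <- tibble::tibble(chain = "a", epitope = 1L, residue = 1:10)
  pred40 <- tibble::tibble(chain = "a", cluster = 1L, residue = c(1:4, 50, 51))
  m40 <- epitope_metrics(pred40, obs)
  expect_equal(m40$v_site, 1)          # 1 matched / 1 predicted
  expect_equal(m40$v_p, 1)

  pred30 <- tibble::tibble(chain = "a", cluster = 1L, residue = c(1:3, 50))
  m30 <- epitope_metrics(pred30, obs)
  expect_equal(m30$antigens$n_matched, 0)  # exactly 30% is not enough
  expect_equal(m30$v_site, 0)
  expect_equal(m30$v_p, 0)
})

test_that("antigen correctness needs all epitopes matched and equal counts", {
  obs <- dplyr::bind_rows(
    tibble::tibble(chain = "a", epitope = 1L, residue = 1:10),
    tibble::tibble(chain = "a", epitope = 2L, residue = 21:30))
  two <- dplyr::bind_rows(
    tibble::tibble(chain = "a", cluster = 1L, residue = 1:5),
    tibble::tibble(chain = "a", cluster = 2L, residue = 21:25))
  m2 <- epitope_metrics(two, obs)
  expect_true(m2$antigens$correct)
  expect_equal(m2$v_site, 1)

  three <- dplyr::bind_rows(two,
    tibble::tibble(chain = "a", cluster = 3L, residue = 60:62))
  m3 <- epitope_metrics(three, obs)
  expect_false(m3$antigens$correct)   # both matched but counts differ
  expect_equal(m3$antigens$n_matched, 2)
  expect_equal(m3$v_site, 2 / 3)

  # no predictions at all: incorrect antigen, no V_site denominator
  none <- tibble::tibble(chain = character(0), cluster = integer(0),
                         residue = integer(0))
  m0 <- epitope_metrics(none, obs)
  expect_true(is.na(m0$v_site))
  expect_equal(m0$v_p, 0)
})

test_that("epitope metrics ignore cluster and epitope ordering", {
  withr::with_seed(43, {
    obs <- dplyr::bind_rows(
      tibble::tibble(chain = "a", epitope = 1L, residue = 1:8),
      tibble::tibble(chain = "a", epitope = 2L, residue = 31:40),
      tibble::tibble(chain = "b", epitope = 1L, residue = 5:12))
    pred <- dplyr::bind_rows(
      tibble::tibble(chain = "a", cluster = 1L, residue = 1:6),
      tibble::tibble(chain = "a", cluster = 2L, residue = 33:38),
      tibble::tibble(chain = "b", cluster = 1L, residue = 9:15))
    base <- epitope_metrics(pred, obs)
    shuffled <- epitope_metrics(pred[sample(nrow(pred)), ],
                                obs[sample(nrow(obs)), ])
    expect_equal(base$v_site, shuffled$v_site)
    expect_equal(base$v_p, shuffled$v_p)
  })
})

test_that("greedy matching is one-to-one by descending coverage", {
  obs <- dplyr::bind_rows(
    tibble::tibble(chain = "a", epitope = 1L, residue = 1:10),
    tibble::tibble(chain = "a", epitope = 2L, residue = 8:17))
  # cluster 1 overlaps both epitopes; it must pair with the better one only
  pred <- dplyr::bind_rows(
    tibble::tibble(chain = "a", cluster = 1L, residue = 4:12),
    tibble::tibble(chain = "a", cluster = 2L, residue = 13:17))
  m <- epitope_metrics(pred, obs)
  expect_equal(nrow(m$matches), 2)
  expect_equal(m$matches$cluster[m$matches$epitope == "1"], "1")
  expect_equal(m$matches$cluster[m$matches$epitope == "2"], "2")
})

test_that("leave-one-antigen-out builds one fold per chain", {
  withr::with_seed(44, {
    n_per <- 40
    mk <- function(ch, seed) {
      withr::with_seed(seed, {
        y <- rbinom(n_per, 1, 0.2)
        x <- matrix(rnorm(n_per * 4), n_per, 4)
        x[, 1] <- x[, 1] + 2.5 * y
        colnames(x) <- paste0("f", 1:4)
        dplyr::bind_cols(tibble::tibble(chain = ch,
                                        residue = seq_len(n_per),
                                        label = y),
                         tibble::as_tibble(x))
      })
    }
    enc <- dplyr::bind_rows(mk("a", 1), mk("b", 2), mk("c", 3))
    cv <- loocv(enc, rounds = 2, gamma = 0.25, seed = 7)
    expect_equal(nrow(cv$per_chain), 3)
    expect_setequal(cv$per_chain$chain, c("a", "b", "c"))
    expect_equal(nrow(cv$scores), nrow(enc))
    expect_true(cv$mean_auc > 0.8)

    # duplicating a chain under a new id adds exactly one fold
    extra <- mk("a", 1)
    extra$chain <- "d"
    cv2 <- loocv(dplyr::bind_rows(enc, extra), rounds = 2, gamma = 0.25,
                 seed = 7)
    expect_equal(nrow(cv2$per_chain), 4)
  })
  expect_error(loocv(tibble::tibble(chain = "a", label = 1, f1 = 0)),
               class = "cbep_config_error")
})

test_that("single-class held-out chains are excluded from the AUC mean", {
  withr::with_seed(45, {
    mk <- function(ch, y) {
      x <- matrix(rnorm(20 * 3), 20, 3)
      x[, 1] <- x[, 1] + 2 * y
      colnames(x) <- paste0("f", 1:3)
      dplyr::bind_cols(tibble::tibble(chain = ch, residue = 1:20, label = y),
                       tibble::as_tibble(x))
    }
    enc <- dplyr::bind_rows(mk("a", rbinom(20, 1, 0.3)),
                            mk("b", rbinom(20, 1, 0.3)),
                            mk("c", rep(0L, 20)))
    expect_warning(cv <- loocv(enc, rounds = 2, gamma = 0.3, seed = 1),
                   "single-class")
    expect_true(is.na(cv$per_chain$auc[cv$per_chain$chain == "c"]))
    expect_false(is.na(cv$mean_auc))
  })
})
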