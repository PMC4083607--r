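test_that("backbone geometry obeys spacing and exclusion constraints", {
  coords <- generate_structure(60, seed = 51)
  steps <- sqrt(rowSums(diff(coords)^2))
  expect_equal(steps, rep(3.8, 59), tolerance = 1e-9)
  d <- as.matrix(dist(coords))
  nonconsec <- abs(row(d) - col(d)) > 1
  expect_gte(min(d[nonconsec]), 4)
  expect_equal(coords, generate_structure(60, seed = 51))
  expect_error(generate_structure(5), class = "cbep_config_error")
})

test_that("planted patches are compact, separated, and cover extremes", {
  coords <- generate_structure(180, seed = 52)
  ids <- plant_epitopes(coords, 2, patch_radius = 9.5,
                        min_separation = 50, seed = 53)
  expect_equal(sort(unique(ids[ids > 0])), 1:2)
  cents <- t(vapply(1:2, function(k)
    colMeans(coords[ids == k, , drop = FALSE]), numeric(3)))
  # patch centroids inherit the seed separation minus patch extent
  expect_gte(sqrt(sum((cents[1, ] - cents[2, ])^2)), 50 - 2 * 9.5)
  for (k in 1:2) {
    expect_lte(cbep:::coord_diameter(coords[ids == k, , drop = FALSE]),
               2 * 9.5)
  }

  # a radius covering the whole chain labels every residue
  small <- generate_structure(20, seed = 54)
  all_ids <- plant_epitopes(small, 1, patch_radius = 1e3,
                            min_separation = 10, seed = 55)
  expect_true(all(all_ids == 1))
})

test_that("recovered R_avg agrees with the generator's own expectation", {
  # Monte-Carlo oracle: mean member-to-centroid distance over many planted
  # patches drawn from the generator itself
  withr::with_seed(56, {
    ds <- purrr::map_dbl(1:30, function(i) {
      coords <- generate_structure(120)
      ids <- plant_epitopes(coords, 1, patch_radius = 9.5,
                            min_separation = 50)
      xyz <- coords[ids == 1, , drop = FALSE]
      cen <- colMeans(xyz)
      mean(sqrt(rowSums((xyz - matrix(cen, nrow(xyz), 3, TRUE))^2)))
    })
  })
  expectation <- mean(ds)
  recs <- cached_dataset("default", n_antigens = 6, seed = 57)
  expect_lt(abs(compute_r_avg(recs) - expectation), 3)
})

test_that("dataset-level imbalance tracks the configured positive fraction", {
  recs <- cached_dataset("default", n_antigens = 6, seed = 57)
  labels <- unlist(purrr::map(recs, "labels"))
  frac <- mean(labels)
  expect_gte(frac, 0.5 * 0.06)
  expect_lte(frac, 1.5 * 0.06)
})

test_that("every emitted file round-trips through its reader", {
  dir <- file.path(tempdir(), "cbep_rt")
  simulate_dataset(dir, n_antigens = 2, length_range = c(60, 80),
                   seed = 58)
  recs <- load_dataset(dir)
  expect_length(recs, 2)
  for (rec in recs) {
    len <- nchar(rec$sequence)
    # writing what we loaded and re-reading is the identity
    p2 <- withr::local_tempfile(fileext = ".pssm")
    write_pssm(rec$pssm, rec$sequence, p2)
    expect_identical(unname(read_pssm(p2, len)[, ]), unname(rec$pssm[, ]))
    s2 <- withr::local_tempfile(fileext = ".ss2")
    write_ss2(rec$ss2, rec$sequence, s2)
    expect_equal(unname(read_ss2(s2, len)[, ]), unname(rec$ss2[, ]))
    d2 <- withr::local_tempfile(fileext = ".diso")
    write_disorder(rec$disorder, rec$sequence, d2)
    expect_identical(read_disorder(d2, len), rec$disorder)
    b2 <- withr::local_tempfile(fileext = ".pdb")
    write_ca_pdb(rec$coords, rec$sequence, "A", b2)
    expect_equal(unclass(read_ca_coords(b2, "A"))[, ],
                 unclass(rec$coords)[, ], ignore_attr = TRUE)
    expect_equal(rowSums(rec$ss2), rep(1, len), tolerance = 1e-9)
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(length(manifest$chains), 2)
  expect_equal(manifest$generator$seed, 58)
})

test_that("planted epitopes are recoverable at the default threshold", {
  recs <- cached_dataset("default", n_antigens = 6, seed = 57)
  for (rec in recs) {
    for (k in setdiff(unique(rec$epitope_ids), 0L)) {
      expect_lte(cbep:::coord_diameter(
        rec$coords[rec$epitope_ids == k, , drop = FALSE]), 2 * 9.5)
    }
  }
})
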