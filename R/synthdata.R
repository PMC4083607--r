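#' Generate a self-avoiding C-alpha backbone
#'
#' Random-walk backbone with 3.8 Angstrom consecutive C-alpha spacing, an
#' exclusion radius between non-consecutive residues, and mild directional
#' persistence so chains extend enough to host several well-separated
#' surface patches.
#'
#' @param length Number of residues (>= 10).
#' @param step Consecutive C-alpha spacing in Angstrom (default 3.8).
#' @param exclusion Minimum distance between non-consecutive residues
#'   (default 4).
#' @param persistence Weight of the previous step direction in the next
#'   step's direction (0 = pure random walk; default 0.6).
#' @param seed Seed for reproducibility.
#' @param max_restarts Full-walk restarts before giving up (default 50).
#' @return A `length` x 3 coordinate matrix.
#' @export
generate_structure <- function(length, step = 3.8, exclusion = 4,
                               persistence = 0.6, seed = NULL,
                               max_restarts = 50) {
  if (length < 10) {
    abort("chain length must be at least 10", class = "cbep_config_error")
  }
  with_seed_or_global(seed, {
    for (attempt in seq_len(max_restarts)) {
      coords <- matrix(NA_real_, nrow = length, ncol = 3,
                       dimnames = list(NULL, c("x", "y", "z")))
      coords[1, ] <- 0
      prev_dir <- c(1, 0, 0)
      failed <- FALSE
      for (i in 2:length) {
        placed <- FALSE
        for (try in seq_len(100)) {
          raw <- rnorm(3)
          dir <- persistence * prev_dir + (1 - persistence) * raw / sqrt(sum(raw^2))
          dir <- dir / sqrt(sum(dir^2))
          cand <- coords[i - 1, ] + step * dir
          if (i > 2) {
            d2 <- rowSums((coords[seq_len(i - 2), , drop = FALSE] -
                             matrix(cand, i - 2, 3, byrow = TRUE))^2)
            if (min(d2) < exclusion^2) next
          }
          coords[i, ] <- cand
          prev_dir <- dir
          placed <- TRUE
          break
        }
        if (!placed) {
          failed <- TRUE
          break
        }
      }
      if (!failed) return(coords)
    }
    abort("self-avoiding walk failed after restarts",
          class = "cbep_generation_error")
  })
}

#' Plant spatial epitope patches on a backbone
#'
#' Chooses `n_epitopes` seed residues whose C-alpha positions are pairwise
#' at least `min_separation` apart and labels every residue within
#' `patch_radius` of a seed as a member of that epitope. When the
#' separation constraint cannot be met the patch count is reduced with a
#' warning.
#'
#' @param coords Backbone coordinate matrix from [generate_structure()].
#' @param n_epitopes Number of patches to plant.
#' @param patch_radius Patch radius in Angstrom (default 9.5).
#' @param min_separation Minimum seed-to-seed distance in Angstrom
#'   (default 50).
#' @param seed Seed for reproducibility.
#' @return Integer vector of per-residue epitope ids (0 = background);
#'   the realized patch count is `max()` of the vector.
#' @export
plant_epitopes <- function(coords, n_epitopes, patch_radius = 9.5,
                           min_separation = 50, seed = NULL) {
  n <- nrow(coords)
  with_seed_or_global(seed, {
    candidates <- sample.int(n)
    seeds <- integer(0)
    for (cand in candidates) {
      if (length(seeds) == n_epitopes) break
      if (all(vapply(seeds, function(s)
        euclidean(coords[s, ], coords[cand, ]) >= min_separation,
        logical(1)))) {
        seeds <- c(seeds, cand)
      }
    }
    if (length(seeds) < n_epitopes) {
      warn(sprintf("only %d of %d epitope seeds satisfy %.0f A separation",
                   length(seeds), n_epitopes, min_separation))
    }
    epitope_ids <- integer(n)
    for (k in seq_along(seeds)) {
      d <- sqrt(rowSums((coords - matrix(coords[seeds[k], ], n, 3,
                                         byrow = TRUE))^2))
      epitope_ids[d <= patch_radius & epitope_ids == 0L] <- k
    }
    epitope_ids
  })
}

# Class-conditional profile emulation.  The discriminative signal is
# injected at the raw-profile level (PSSM scores, secondary-structure
# concentrations, disorder rate) so the entire encoding path is exercised
# end-to-end; `effect` is expressed in units of the PSSM score sd.
synth_profiles <- function(labels, effect, informative_cols, score_sd = 2) {
  n <- length(labels)
  shift <- matrix(0, n, 20)
  shift[labels == 1, informative_cols] <- effect * score_sd
  pssm <- round(matrix(rnorm(n * 20, sd = score_sd), n, 20) + shift)
  pssm <- pmin(pmax(pssm, -13), 13)
  colnames(pssm) <- pssm_columns

  conc <- matrix(3, n, 3, dimnames = list(NULL, c("helix", "coil", "strand")))
  conc[labels == 1, "coil"] <- 3 + effect
  draws <- matrix(rgamma(n * 3, shape = conc), n, 3)
  ss2 <- round(draws / rowSums(draws), 3)
  # fix the largest component so rows sum to exactly 1 at 3 decimals,
  # keeping the written .ss2 file an exact round trip
  for (i in seq_len(n)) {
    j <- which.max(ss2[i, ])
    ss2[i, j] <- round(ss2[i, j] + (1 - sum(ss2[i, ])), 3)
  }
  colnames(ss2) <- c("helix", "coil", "strand")

  p_dis <- ifelse(labels == 1,
                  stats::plogis(stats::qlogis(0.05) + 0.7 * effect), 0.05)
  disorder <- rbinom(n, 1, p_dis)
  list(pssm = pssm, ss2 = ss2, disorder = disorder)
}

#' Simulate a complete synthetic antigen dataset on disk
#'
#' Generates antigen chains with planted spatial epitope patches and emits
#' every upstream file the pipeline consumes — FASTA, blastpgp-style PSSM,
#' PSIPRED-style .ss2, DISOPRED-style disorder files, C-alpha PDB files,
#' the epitope annotation TSV, and a JSON manifest carrying the generator
#' configuration and ground truth. Per-chain epitope counts and lengths
#' are drawn from the configured ranges, and draws are retried until the
#' realized positive fraction falls within +/-50% of the target (the
#' closest draw is kept otherwise). The defaults emulate the class
#' imbalance (~6% antigenic determinant residues) and patch geometry
#' (R_avg around the patch scale, patches separated well beyond the
#' clustering threshold) of real benchmark antigen sets.
#'
#' @param dir Output directory (created if needed).
#' @param n_antigens Number of chains (default 8).
#' @param length_range Chain length range (default c(150, 250)).
#' @param positive_fraction Target fraction of antigenic determinant
#'   residues (default 0.06).
#' @param epitopes_range Range of patches per chain (default c(1, 3)).
#' @param patch_radius Patch radius in Angstrom (default 9.5).
#' @param min_separation Minimum patch seed separation (default 50).
#' @param class_effect_size Class-conditional mean shift in the
#'   profile-generating distributions, in units of the PSSM score sd
#'   (0 = no signal; default 2, a clearly separable regime).
#' @param seed Root seed for the whole dataset.
#' @return Invisibly, the manifest list (chain ids, planted epitope counts,
#'   positive fractions, file paths).
#' @export
simulate_dataset <- function(dir, n_antigens = 8,
                             length_range = c(150, 250),
                             positive_fraction = 0.06,
                             epitopes_range = c(1, 3),
                             patch_radius = 9.5, min_separation = 50,
                             class_effect_size = 2, seed = NULL) {
  stopifnot(positive_fraction > 0, positive_fraction < 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  informative_cols <- with_seed_or_global(derive_seed(seed, 0),
                                          sort(sample.int(20, 8)))
  records <- purrr::map(seq_len(n_antigens), function(i) {
    chain_seed <- derive_seed(seed, i)
    with_seed_or_global(chain_seed, {
      best <- NULL
      lens <- seq(length_range[1], length_range[2])
      gs <- seq(epitopes_range[1], epitopes_range[2])
      for (try in seq_len(20)) {
        len <- lens[sample.int(length(lens), 1)]
        g <- gs[sample.int(length(gs), 1)]
        coords <- generate_structure(len)
        epitope_ids <- plant_epitopes(coords, g, patch_radius,
                                      min_separation)
        frac <- mean(epitope_ids > 0)
        cand <- list(coords = coords, epitope_ids = epitope_ids,
                     frac = frac, len = len)
        if (is.null(best) ||
            abs(frac - positive_fraction) <
              abs(best$frac - positive_fraction)) {
          best <- cand
        }
        if (frac >= 0.5 * positive_fraction &&
            frac <= 1.5 * positive_fraction) break
      }
      labels <- as.integer(best$epitope_ids > 0)
      sequence <- paste(sample(aa_standard, best$len, replace = TRUE),
                        collapse = "")
      prof <- synth_profiles(labels, class_effect_size, informative_cols)
      antigen_record(sprintf("syn%02d", i), sequence,
                     epitope_ids = best$epitope_ids,
                     coords = round(best$coords, 3),
                     pssm = prof$pssm, ss2 = prof$ss2,
                     disorder = prof$disorder)
    })
  })

  write_fasta(records, file.path(dir, "antigens.fasta"))
  for (rec in records) {
    write_pssm(rec$pssm, rec$sequence, file.path(dir, paste0(rec$id, ".pssm")))
    write_ss2(rec$ss2, rec$sequence, file.path(dir, paste0(rec$id, ".ss2")))
    write_disorder(rec$disorder, rec$sequence,
                   file.path(dir, paste0(rec$id, ".diso")))
    write_ca_pdb(rec$coords, rec$sequence, "A",
                 file.path(dir, paste0(rec$id, ".pdb")))
  }
  write_epitope_annotations(records, file.path(dir, "annotations.tsv"))

  manifest <- list(
    generator = list(n_antigens = n_antigens, length_range = length_range,
                     positive_fraction = positive_fraction,
                     epitopes_range = epitopes_range,
                     patch_radius = patch_radius,
                     min_separation = min_separation,
                     class_effect_size = class_effect_size,
                     seed = seed, informative_pssm_columns = informative_cols),
    chains = purrr::map(records, function(rec) {
      list(id = rec$id, length = nchar(rec$sequence),
           n_epitopes = max(rec$epitope_ids),
           positive_fraction = mean(rec$labels))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a simulated (or equivalently laid out) antigen dataset
#'
#' Reads back a dataset directory written by [simulate_dataset()] through
#' the package's format parsers, reattaching profiles, coordinates and
#' annotations to each chain.
#'
#' @param dir Dataset directory.
#' @return A list of fully populated [antigen_record()]s.
#' @export
load_dataset <- function(dir) {
  records <- read_fasta(file.path(dir, "antigens.fasta"))
  ann_path <- file.path(dir, "annotations.tsv")
  annotations <- if (file.exists(ann_path)) {
    read_epitope_annotations(ann_path)
  } else {
    NULL
  }
  purrr::map(records, function(rec) {
    len <- nchar(rec$sequence)
    pssm <- read_pssm(file.path(dir, paste0(rec$id, ".pssm")), len)
    ss2 <- read_ss2(file.path(dir, paste0(rec$id, ".ss2")), len)
    disorder <- read_disorder(file.path(dir, paste0(rec$id, ".diso")), len)
    coords <- read_ca_coords(file.path(dir, paste0(rec$id, ".pdb")), "A")
    rec <- antigen_record(rec$id, rec$sequence, coords = unclass(coords),
                          pssm = pssm, ss2 = ss2, disorder = disorder)
    if (!is.null(annotations)) rec <- apply_annotations(rec, annotations)
    rec
  })
}
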