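#' Specification for a synthetic tractometry dataset
#'
#' Describes a dataset that emulates the tabular representation of whole-brain
#' fiber-cluster tractometry: per measure, a subjects-by-clusters matrix
#' (default 953 clusters, matching a fine whole-brain parcellation) on a
#' measure-typical scale (FA in \[0, 1\], MD around 1e-3 mm^2/s, streamline
#' counts in the hundreds), with a sparse planted linear signal on a known
#' informative subset, Gaussian label noise at a controlled signal-to-noise
#' ratio, optional zero-inflation emulating empty clusters, and a random
#' assignment of clusters to five anatomical categories.
#'
#' The label is built from standardized latent features:
#' `y_raw = sum_m sum_k w * x + e`, `e ~ N(0, noise_sd^2)`, with the planted
#' weights normalized so the noise-free signal has unit variance; `y_raw` is
#' then rescaled to sample standard deviation 1, giving scores spanning
#' roughly \[-3, 3\]. The maximum achievable test correlation (noise ceiling)
#' is therefore `r_max = 1 / sqrt(1 + noise_sd^2)` in closed form;
#' [noise_sd_for_ceiling()] inverts it. Informative features are spread
#' across the measures so ensembling has complementary information.
#'
#' @param n_subjects Number of subjects.
#' @param n_features Clusters per measure (default 953).
#' @param n_informative Total planted informative features (default 50).
#' @param n_measures Number of measure tables (default 3: FA, MD, NoS).
#' @param noise_sd Label noise standard deviation relative to the
#'   unit-variance signal; default gives a noise ceiling of 0.6.
#' @param zero_inflation Fraction of observed entries set to 0, emulating
#'   empty clusters (default 0.02; use 0 when validating noise ceilings).
#' @param nonlinear If `TRUE`, the signal passes through `tanh` before noise,
#'   giving deep models an edge over linear fits (default `FALSE`).
#' @param measure_names Names of the measure tables.
#' @param score_name Label name stored with the scores (default `"PC1"`).
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the spec.
#' @return A list of class `synthetic_spec`.
#' @seealso [generate_dataset()]
#' @export
synthetic_spec <- function(n_subjects, n_features = 953, n_informative = 50,
                           n_measures = 3,
                           noise_sd = noise_sd_for_ceiling(0.6),
                           zero_inflation = 0.02, nonlinear = FALSE,
                           measure_names = c("FA", "MD", "NoS"),
                           score_name = "PC1", seed = 1) {
  if (n_informative > n_features) abort("n_informative must not exceed n_features")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (zero_inflation < 0 || zero_inflation >= 1) {
    abort("zero_inflation must be in [0, 1)")
  }
  if (length(measure_names) < n_measures) {
    measure_names <- c(measure_names, paste0("M", seq_len(n_measures)))
  }
  structure(
    list(
      n_subjects = n_subjects, n_features = n_features,
      n_informative = n_informative, n_measures = n_measures,
      noise_sd = noise_sd, zero_inflation = zero_inflation,
      nonlinear = nonlinear,
      measure_names = measure_names[seq_len(n_measures)],
      score_name = score_name, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Label-noise level for a target noise ceiling
#'
#' With a unit-variance noise-free signal, additive Gaussian noise of standard
#' deviation `sigma` caps the achievable truth-prediction correlation at
#' `1 / sqrt(1 + sigma^2)`. This returns the `sigma` giving a requested
#' ceiling.
#'
#' @param r_max Target ceiling in (0, 1\].
#' @param signal_var Variance of the noise-free signal (default 1).
#' @return The noise standard deviation.
#' @export
noise_sd_for_ceiling <- function(r_max, signal_var = 1) {
  if (r_max <= 0 || r_max > 1) abort("r_max must be in (0, 1]")
  sqrt(signal_var * (1 / r_max^2 - 1))
}

# Measure-typical affine scales for observed features.
measure_scales <- function(names) {
  lookup <- list(
    FA = c(offset = 0.5, scale = 0.08),
    MD = c(offset = 8.5e-4, scale = 6e-5),
    NoS = c(offset = 600, scale = 120)
  )
  lapply(names, function(nm) lookup[[nm]] %||% c(offset = 0, scale = 1))
}

#' Generate a synthetic tractometry dataset
#'
#' Draws the dataset described by a [synthetic_spec()]: one feature table per
#' measure, a score vector, a feature-to-category map and a ground-truth
#' record (informative feature ids with weights, the noise-free signal, and
#' the closed-form noise ceiling `r_max`).
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `scr_dataset` with elements `tables` (named list
#'   of feature tibbles), `scores` (tibble `subject_id`, `score`),
#'   `category_map` (tibble `feature_id`, `category`) and `truth`.
#' @examples
#' ds <- generate_dataset(synthetic_spec(100, n_features = 20, n_informative = 4,
#'                                       n_measures = 1, seed = 2))
#' ds$truth$r_max
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_subjects
  d <- spec$n_features
  k <- spec$n_informative
  m <- spec$n_measures
  withr::with_seed(spec$seed, {
    subject_ids <- sprintf("sub_%04d", seq_len(n))
    feature_ids <- sprintf("cluster_%04d", seq_len(d))
    # split the informative features across measures (complementary signal)
    k_per <- diff(round(seq(0, k, length.out = m + 1)))
    informative <- lapply(seq_len(m), function(j) sort(sample.int(d, k_per[j])))
    # equal-magnitude, random-sign weights: every planted feature carries the
    # same detectable share of the signal, and the signal variance is 1
    weights <- lapply(k_per, function(kj) {
      sample(c(-1, 1), kj, replace = TRUE) / sqrt(k)
    })
    latent <- lapply(seq_len(m), function(j) {
      matrix(rnorm(n * d), n, d, dimnames = list(subject_ids, feature_ids))
    })
    signal <- Reduce(`+`, lapply(seq_len(m), function(j) {
      drop(latent[[j]][, informative[[j]], drop = FALSE] %*% weights[[j]])
    }))
    if (spec$nonlinear) signal <- tanh(signal) / sd(tanh(signal))
    y_raw <- signal + rnorm(n, sd = spec$noise_sd)
    y <- unname(y_raw / sd(y_raw))
    scales <- measure_scales(spec$measure_names)
    tables <- lapply(seq_len(m), function(j) {
      obs <- scales[[j]]["offset"] + scales[[j]]["scale"] * latent[[j]]
      if (spec$zero_inflation > 0) {
        obs[runif(n * d) < spec$zero_inflation] <- 0
      }
      as_feature_table(
        tibble::tibble(subject_id = subject_ids, !!!as.data.frame(obs)),
        measure_name = spec$measure_names[j]
      )
    })
    names(tables) <- spec$measure_names
    category_map <- tibble::tibble(
      feature_id = feature_ids,
      category = sample(
        c("association", "projection", "commissural", "cerebellar", "superficial"),
        d, replace = TRUE, prob = c(0.28, 0.22, 0.12, 0.15, 0.23)
      )
    )
  })
  truth <- list(
    informative = tibble::tibble(
      measure = rep(spec$measure_names, k_per),
      feature_id = sprintf("cluster_%04d", unlist(informative)),
      weight = unlist(weights)
    ),
    signal = setNames(signal, sprintf("sub_%04d", seq_len(n))),
    r_max = 1 / sqrt(1 + spec$noise_sd^2),
    noise_sd = spec$noise_sd,
    spec = spec
  )
  structure(
    list(
      tables = tables,
      scores = tibble::tibble(
        subject_id = sprintf("sub_%04d", seq_len(n)), score = y
      ),
      category_map = category_map,
      truth = truth
    ),
    class = "scr_dataset"
  )
}

#' @export
print.scr_dataset <- function(x, ...) {
  sp <- x$truth$spec
  cat(sprintf(
    "<scr_dataset> %d subjects x %d features x %d measure(s); %d informative, r_max %.3f\n",
    sp$n_subjects, sp$n_features, sp$n_measures, sp$n_informative, x$truth$r_max
  ))
  invisible(x)
}

#' Write a synthetic dataset to plain-text fixtures
#'
#' Emits one feature CSV per measure (`features_<measure>.csv`), the label CSV
#' (`scores.csv`), the category map (`categories.csv`) and a JSON ground-truth
#' manifest (`truth.json`). Reloading with [read_dataset()] reproduces the
#' matrices exactly.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(dataset$tables)) {
    write_feature_table(dataset$tables[[nm]], file.path(dir, paste0("features_", nm, ".csv")))
  }
  readr::write_csv(dataset$scores, file.path(dir, "scores.csv"))
  readr::write_csv(dataset$category_map, file.path(dir, "categories.csv"))
  truth <- dataset$truth
  manifest <- list(
    informative = truth$informative,
    r_max = truth$r_max,
    noise_sd = truth$noise_sd,
    signal = unname(truth$signal),
    spec = unclass(truth$spec)
  )
  jsonlite::write_json(
    manifest, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Reload a written synthetic dataset
#'
#' @param dir Directory produced by [write_dataset()].
#' @return An `scr_dataset` list (ground truth restored from the manifest).
#' @export
read_dataset <- function(dir) {
  files <- list.files(dir, pattern = "^features_.*\\.csv$", full.names = TRUE)
  measures <- sub("^features_(.*)\\.csv$", "\\1", basename(files))
  manifest <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  ord <- match(manifest$spec$measure_names, measures)
  tables <- lapply(seq_along(ord), function(i) {
    read_feature_table(files[ord[i]], measure_name = measures[ord[i]])
  })
  names(tables) <- measures[ord]
  scores <- read_scores(file.path(dir, "scores.csv"))
  truth <- list(
    informative = tibble::as_tibble(manifest$informative),
    signal = setNames(manifest$signal, scores$subject_id),
    r_max = manifest$r_max,
    noise_sd = manifest$noise_sd,
    spec = structure(manifest$spec, class = "synthetic_spec")
  )
  structure(
    list(
      tables = tables, scores = scores,
      category_map = read_category_map(file.path(dir, "categories.csv")),
      truth = truth
    ),
    class = "scr_dataset"
  )
}
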