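#' Uniform-noise half-widths from replicate spread
#'
#' Robust per-run noise scale for resampling augmentation of a
#' replicated design. The replicate spread of each run is estimated
#' robustly as \eqn{\hat\sigma = IQR/1.349} (quartiles by linear
#' interpolation, `stats::quantile` type 7); the half-width of the
#' injected Uniform(-w, w) noise is then \eqn{w = \sqrt{3}\,\hat\sigma}
#' so that the noise standard deviation matches \eqn{\hat\sigma}
#' (`scale = "sd"`), or the raw IQR itself (`scale = "iqr"`).
#'
#' @param data Replicate data frame with a run identifier column and a
#'   response column.
#' @param response,run Column names of the response and run id.
#' @param pooling `"per-run"` (default): one half-width per run from its
#'   own replicates; `"pooled"`: a single half-width from the IQR of all
#'   run-centered replicate deviations.
#' @param scale `"sd"` (default, sd-matched) or `"iqr"` (raw IQR
#'   half-width).
#' @return Named numeric vector of half-widths, one per run (identical
#'   entries in pooled mode). Constant replicates give 0.
#' @examples
#' d <- data.frame(run = rep(1:2, each = 3), activity = c(10, 10, 10, 217, 222, 284))
#' noise_halfwidth(d)
#' @export
noise_halfwidth <- function(data, response = "activity", run = "run",
                            pooling = c("per-run", "pooled"),
                            scale = c("sd", "iqr")) {
  pooling <- match.arg(pooling)
  scale <- match.arg(scale)
  if (!all(c(response, run) %in% names(data)))
    stop("data must have columns '", run, "' and '", response, "'",
         call. = FALSE)
  y <- data[[response]]
  g <- data[[run]]
  runs <- unique(g)
  cnt <- table(g)
  iqr_scale <- function(v) stats::IQR(v, type = 7) / 1.349
  if (pooling == "per-run") {
    if (any(cnt < 2L))
      stop("per-run mode needs >= 2 replicates per run", call. = FALSE)
    sig <- vapply(runs, function(r) iqr_scale(y[g == r]), numeric(1L))
  } else {
    centered <- y - stats::ave(y, g)
    sig <- rep(iqr_scale(centered), length(runs))
  }
  w <- if (scale == "sd") sqrt(3) * sig else 1.349 * sig
  stats::setNames(w, as.character(runs))
}

#' Resampling-plus-noise augmentation of a replicated design
#'
#' Expands a replicated design dataset by drawing observations uniformly
#' with replacement and adding independent Uniform(-w, w) noise to the
#' resampled response, with w the run's half-width from
#' [noise_halfwidth()]. Factor levels are carried over unchanged, so the
#' augmented set lives on the original design support. Fully
#' reproducible from `seed`.
#'
#' @param data Replicate data frame: run id, factor columns, response.
#' @param target_n Number of augmented samples to produce.
#' @param seed Integer seed (the caller's RNG state is restored).
#' @param factors Character vector of factor column names; defaults to
#'   the names of the attached `bbd_factors` attribute, else to all
#'   columns other than the run/replicate/response columns.
#' @param response,run Column names.
#' @inheritParams noise_halfwidth
#' @return A data frame (class `augmented_data`) with the factor
#'   columns, the noisy response, `source_run` and `sample_id`;
#'   provenance (seed, target size, noise rule, half-widths) in attribute
#'   `"provenance"`.
#' @examples
#' reps <- simulate_bbd_dataset(truth_surface(), replicates = 3, seed = 1)
#' aug <- augment_replicates(reps, target_n = 750, seed = 2)
#' nrow(aug)  # 750
#' @export
augment_replicates <- function(data, target_n = 750, seed = NULL,
                               factors = NULL, response = "activity",
                               run = "run",
                               pooling = c("per-run", "pooled"),
                               scale = c("sd", "iqr")) {
  pooling <- match.arg(pooling)
  scale <- match.arg(scale)
  if (nrow(data) == 0L) stop("empty replicate dataset", call. = FALSE)
  if (target_n < 1 || target_n != round(target_n))
    stop("target_n must be a positive integer", call. = FALSE)
  if (is.null(factors)) {
    fs <- attr(data, "factors")
    factors <- if (!is.null(fs)) factor_names(fs)
               else setdiff(names(data), c(run, "rep", response))
  }
  if (!all(c(factors, response, run) %in% names(data)))
    stop("missing columns in replicate data", call. = FALSE)
  w <- noise_halfwidth(data, response, run, pooling, scale)
  out <- with_seed(seed, {
    idx <- sample.int(nrow(data), target_n, replace = TRUE)
    src_run <- data[[run]][idx]
    noise <- stats::runif(target_n, -1, 1) * w[as.character(src_run)]
    d <- data[idx, factors, drop = FALSE]
    d[[response]] <- data[[response]][idx] + noise
    d$source_run <- src_run
    d$sample_id <- seq_len(target_n)
    rownames(d) <- NULL
    d
  })
  attr(out, "factors") <- attr(data, "factors")
  attr(out, "provenance") <- list(
    seed = seed, target_n = target_n,
    noise_rule = sprintf("uniform(-w, w), w = %s, %s, quantile type 7",
                         if (scale == "sd") "sqrt(3) * IQR/1.349" else "IQR",
                         pooling),
    halfwidths = w,
    caveat = paste("augmentation perturbs the error structure;",
                   "sample-level splits of augmented data share source",
                   "observations across train/test"))
  class(out) <- c("augmented_data", "data.frame")
  out
}

#' Train/test split of an augmented dataset
#'
#' `mode = "sample"` shuffles samples and cuts at the fraction (the test
#' side is the floor of `n * test_fraction`); `mode = "run"` assigns
#' whole source runs to one side, a leakage-safe alternative for honest
#' generalization estimates since sample-level splits of augmented data
#' place noisy copies of the same observation on both sides.
#'
#' @param data An `augmented_data` frame (any data frame with a
#'   `source_run` column works).
#' @param test_fraction Fraction of samples on the test side (0, 1).
#' @param mode `"sample"` (default) or `"run"`.
#' @param seed Integer seed.
#' @return A list of class `augment_split` with elements `train` and
#'   `test` (disjoint, union = input) and attributes `mode` and `seed`.
#' @examples
#' reps <- simulate_bbd_dataset(truth_surface(), seed = 1)
#' aug <- augment_replicates(reps, 750, seed = 2)
#' sp <- split_augmented(aug, 0.2, seed = 3)
#' vapply(sp, nrow, integer(1))  # 600, 150
#' @export
split_augmented <- function(data, test_fraction = 0.2,
                            mode = c("sample", "run"), seed = NULL) {
  mode <- match.arg(mode)
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  n <- nrow(data)
  test_idx <- with_seed(seed, {
    if (mode == "sample") {
      sample.int(n)[seq_len(floor(n * test_fraction))]
    } else {
      runs <- unique(data$source_run)
      if (length(runs) < 2L)
        stop("run-level splitting needs >= 2 distinct runs", call. = FALSE)
      perm <- sample(runs)
      sizes <- cumsum(vapply(perm, function(r) sum(data$source_run == r),
                             numeric(1L)))
      k <- which.min(abs(sizes - n * test_fraction))
      which(data$source_run %in% perm[seq_len(k)])
    }
  })
  out <- list(train = data[-test_idx, , drop = FALSE],
              test = data[test_idx, , drop = FALSE])
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  attr(out, "factors") <- attr(data, "factors")
  class(out) <- "augment_split"
  out
}

#' @export
print.augment_split <- function(x, ...) {
  cat(sprintf("%s-level split: %d train / %d test\n", attr(x, "mode"),
              nrow(x$train), nrow(x$test)))
  invisible(x)
}
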