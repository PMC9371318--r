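# Deterministic sub-stream seeds. One master seed is hashed together with
# a variable-length key (replicate, level, method, ...) so that each block
# of draws has its own stream: adding a method to a fixture never perturbs
# another method's draws, and fixtures are byte-identical per seed.
substream_seed <- function(seed, ...) {
  key <- paste(c(format(seed), ...), collapse = "|")
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

#' Biological-channel parameters for the expression simulator
#'
#' Describes a Hill-type dose response from an environmental stimulus
#' (e.g. inducer concentration) to mean expression, with gamma-distributed
#' cell-to-cell variability: at stimulus c the mean is
#' \eqn{\mu(c) = basal + (induced - basal) c^n / (K^n + c^n)} and per-cell
#' expression is gamma with that mean and coefficient of variation
#' \code{biological_cv}. The gamma family is a standard skewed-positive
#' model for gene expression; the capacity estimator itself is
#' distribution-free.
#'
#' @param basal_mean mean expression with no stimulus (expression units).
#' @param induced_mean mean expression at saturating stimulus; must exceed
#'   \code{basal_mean}.
#' @param half_max_stimulus stimulus K giving the half-maximal response.
#' @param hill_coefficient Hill exponent n (response steepness).
#' @param biological_cv coefficient of variation of per-cell expression at
#'   fixed stimulus.
#' @param stimulus_levels ordered stimulus ladder; the default is 8 levels
#'   log-spaced around K, spanning near-basal to near-saturating response.
#' @return An object of class \code{"bio_channel_params"}.
#' @export
bio_channel_params <- function(basal_mean = 20,
                               induced_mean = 2000,
                               half_max_stimulus = 50,
                               hill_coefficient = 2,
                               biological_cv = 0.3,
                               stimulus_levels = half_max_stimulus * 2^seq(-4, 4, length.out = 8)) {
  if (!(induced_mean > basal_mean && basal_mean > 0)) {
    stop("need induced_mean > basal_mean > 0", call. = FALSE)
  }
  if (biological_cv <= 0) stop("biological_cv must be positive", call. = FALSE)
  if (half_max_stimulus <= 0 || hill_coefficient <= 0) {
    stop("half_max_stimulus and hill_coefficient must be positive", call. = FALSE)
  }
  if (length(stimulus_levels) < 2L || any(stimulus_levels < 0) ||
      is.unsorted(stimulus_levels, strictly = TRUE)) {
    stop("stimulus_levels must be at least 2 strictly increasing non-negative values",
         call. = FALSE)
  }
  structure(list(basal_mean = basal_mean, induced_mean = induced_mean,
                 half_max_stimulus = half_max_stimulus,
                 hill_coefficient = hill_coefficient,
                 biological_cv = biological_cv,
                 stimulus_levels = stimulus_levels),
            class = "bio_channel_params")
}

#' Measurement-channel parameters for the expression simulator
#'
#' Describes the degradation a measurement process applies to true
#' expression x: \eqn{y = e \cdot x \cdot \exp(\sigma_m Z_1) + b + \sigma_b Z_2}
#' with independent standard normals per cell — a multiplicative
#' (log-normal) detection-noise term scaled by transfer efficiency, plus an
#' additive Gaussian background. The defaults describe a perfect
#' (noise-free, identity) measurement; degrade from there.
#'
#' @param efficiency multiplicative signal transfer in (0, 1].
#' @param multiplicative_noise_sd log-scale SD of detection noise (>= 0).
#' @param background_mean mean additive background signal.
#' @param background_sd SD of the additive background (>= 0).
#' @return An object of class \code{"measurement_channel_params"}.
#' @export
measurement_channel_params <- function(efficiency = 1,
                                       multiplicative_noise_sd = 0,
                                       background_mean = 0,
                                       background_sd = 0) {
  if (!(efficiency > 0 && efficiency <= 1)) stop("efficiency must be in (0, 1]", call. = FALSE)
  if (multiplicative_noise_sd < 0 || background_sd < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  structure(list(efficiency = efficiency,
                 multiplicative_noise_sd = multiplicative_noise_sd,
                 background_mean = background_mean,
                 background_sd = background_sd),
            class = "measurement_channel_params")
}

hill_mean <- function(bio, c) {
  n <- bio$hill_coefficient
  occ <- if (c == 0) 0 else c^n / (bio$half_max_stimulus^n + c^n)
  bio$basal_mean + (bio$induced_mean - bio$basal_mean) * occ
}

#' Simulate true per-cell expression across a stimulus ladder
#'
#' Draws \code{n_cells_per_level} gamma-distributed expression values at
#' each stimulus level of the biological channel. Reproducible: the same
#' seed gives identical draws, level by level.
#'
#' @param bio a \code{\link{bio_channel_params}} object.
#' @param n_cells_per_level cells per stimulus level.
#' @param seed integer seed.
#' @return A \code{\link{sample_set}} of true expression values, one entry
#'   per stimulus level (named by stimulus value).
#' @export
simulate_expression <- function(bio, n_cells_per_level = 1000, seed = 1) {
  stopifnot(inherits(bio, "bio_channel_params"))
  if (n_cells_per_level < 1L) stop("n_cells_per_level must be positive", call. = FALSE)
  cv <- bio$biological_cv
  shape <- 1 / cv^2
  vals <- lapply(seq_along(bio$stimulus_levels), function(i) {
    mu <- hill_mean(bio, bio$stimulus_levels[i])
    set.seed(substream_seed(seed, "expression", i))
    stats::rgamma(n_cells_per_level, shape = shape, scale = mu / shape)
  })
  names(vals) <- format(bio$stimulus_levels, trim = TRUE)
  sample_set(vals)
}

#' Pass true expression values through a measurement channel
#'
#' Applies efficiency loss, log-normal multiplicative detection noise and
#' additive Gaussian background to every cell of a sample set, level by
#' level, with a fresh sub-stream per level.
#'
#' @param true_values a \code{\link{sample_set}} of true expression values.
#' @param meas a \code{\link{measurement_channel_params}} object.
#' @param seed integer seed.
#' @return A \code{\link{sample_set}} of measured values with the same
#'   structure as the input.
#' @export
simulate_measurement <- function(true_values, meas, seed = 1) {
  stopifnot(inherits(true_values, "sample_set"),
            inherits(meas, "measurement_channel_params"))
  vals <- lapply(seq_along(true_values$values_by_input), function(i) {
    x <- true_values$values_by_input[[i]]
    set.seed(substream_seed(seed, "measurement", i))
    z1 <- stats::rnorm(length(x))
    z2 <- stats::rnorm(length(x))
    meas$efficiency * x * exp(meas$multiplicative_noise_sd * z1) +
      meas$background_mean + meas$background_sd * z2
  })
  names(vals) <- names(true_values$values_by_input)
  sample_set(vals)
}

#' Generate a split-sample study fixture
#'
#' Emulates a split-sample design: for each biological replicate, one
#' shared set of true expression values is drawn per stimulus level, and
#' every measurement method is applied to those same cells. Method
#' comparisons on the resulting table therefore share one biological
#' channel, exactly as when a replicate culture is divided across
#' measurement workflows.
#'
#' @param method_specs named list of
#'   \code{\link{measurement_channel_params}}, one per method; names are
#'   the method labels.
#' @param bio a \code{\link{bio_channel_params}} object (shared biology).
#' @param n_replicates number of biological replicates (default 3).
#' @param n_cells_per_level cells per (level, replicate) (default 1000).
#' @param seed master integer seed; all randomness derives from it via
#'   per-(replicate, level, method) sub-streams.
#' @param measurand measurand label written to the table (default "RNA").
#' @return A data frame with columns \code{method, measurand, replicate,
#'   input_level, value}, one row per (cell, method).
#' @export
generate_split_sample_fixture <- function(method_specs, bio = bio_channel_params(),
                                          n_replicates = 3, n_cells_per_level = 1000,
                                          seed = 1, measurand = "RNA") {
  if (!is.list(method_specs) || length(method_specs) < 1L || is.null(names(method_specs)) ||
      any(names(method_specs) == "")) {
    stop("method_specs must be a non-empty named list of measurement_channel_params",
         call. = FALSE)
  }
  for (m in method_specs) {
    if (!inherits(m, "measurement_channel_params")) {
      stop("every method spec must be a measurement_channel_params object", call. = FALSE)
    }
  }
  out <- vector("list", n_replicates * length(method_specs))
  k <- 0L
  for (r in seq_len(n_replicates)) {
    truth <- simulate_expression(bio, n_cells_per_level,
                                 seed = substream_seed(seed, "replicate", r))
    for (lab in names(method_specs)) {
      measured <- simulate_measurement(truth, method_specs[[lab]],
                                       seed = substream_seed(seed, "replicate", r,
                                                             "method", lab))
      k <- k + 1L
      out[[k]] <- data.frame(
        method = lab,
        measurand = measurand,
        replicate = paste0("rep", r),
        input_level = rep(names(measured$values_by_input), measured$n_cells),
        value = unlist(measured$values_by_input, use.names = FALSE),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
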