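# Synthetic diurnal expression profiles: raised-cosine bump waveforms on
# the 3 h sampling grid, emulating the qualitative profile classes seen in
# the measured data (dawn peaks, dusk peaks, late-night/early-morning
# double peaks, transition steps, 12 h rhythms), so the whole pipeline is
# testable without any download.

#' Specify one synthetic diurnal profile
#'
#' @param gene_id gene identifier.
#' @param shape one of `"single_peak"`, `"double_peak"`,
#'   `"step_at_transition"`, `"flat"`.
#' @param peak_time_h phase of the (first) peak, hours in `[0, period)`.
#'   For `step_at_transition` this is the step-up time.
#' @param width_h half-width of the raised-cosine bump (hours).
#' @param peak2_time_h,amplitude2,width2_h second bump of a double peak
#'   (defaults: 6 h after the first, same size).
#' @param amplitude,baseline,noise_sd waveform parameters (all >= 0);
#'   `noise_sd` is the SD of additive Gaussian noise, clipped at zero.
#' @param period_h rhythm period; 24 (default) or 12 for GWD-like
#'   profiles.
#' @return A `profile_spec` (a one-row list).
#' @export
profile_spec <- function(gene_id,
                         shape = c("single_peak", "double_peak",
                                   "step_at_transition", "flat"),
                         peak_time_h = 12, amplitude = 1, baseline = 0,
                         noise_sd = 0, width_h = 7.5,
                         peak2_time_h = (peak_time_h + 6) %% 24,
                         amplitude2 = amplitude, width2_h = width_h,
                         period_h = 24) {
  shape <- match.arg(shape)
  if (amplitude < 0 || baseline < 0 || noise_sd < 0 || amplitude2 < 0)
    stop("amplitude, baseline and noise_sd must be >= 0")
  if (peak_time_h < 0 || peak_time_h >= period_h)
    stop("peak_time_h must lie within one cycle")
  structure(list(gene_id = gene_id, shape = shape,
                 peak_time_h = peak_time_h, amplitude = amplitude,
                 baseline = baseline, noise_sd = noise_sd,
                 width_h = width_h, peak2_time_h = peak2_time_h,
                 amplitude2 = amplitude2, width2_h = width2_h,
                 period_h = period_h),
            class = "profile_spec")
}

# raised-cosine bump, circular in t with the given period
.bump <- function(t, peak, width, period) {
  d <- (t - peak) %% period
  d <- pmin(d, period - d)
  ifelse(d < width, cos(pi * d / (2 * width))^2, 0)
}

.eval_spec <- function(spec, t) {
  s <- spec
  base <- switch(s$shape,
    flat = rep(0, length(t)),
    single_peak = s$amplitude * .bump(t, s$peak_time_h, s$width_h, s$period_h),
    double_peak = s$amplitude * .bump(t, s$peak_time_h, s$width_h, s$period_h) +
      s$amplitude2 * .bump(t, s$peak2_time_h, s$width2_h, s$period_h),
    step_at_transition = {
      on <- ((t - s$peak_time_h) %% s$period_h) < s$period_h / 2
      s$amplitude * as.numeric(on)
    },
    stop("unknown shape: ", s$shape))
  s$baseline + base
}

#' Generate synthetic expression profiles
#'
#' Evaluates each profile specification on the sampling grid and adds
#' Gaussian noise (clipped at zero). Reproducible for a fixed seed.
#'
#' @param specs list of [profile_spec()] objects.
#' @param time_points_h sampling grid (default 0, 3, ..., 24: nine points).
#' @param seed integer RNG seed.
#' @return An `expression_series`.
#' @export
generate_profiles <- function(specs, time_points_h = seq(0, 24, by = 3),
                              seed = 1L) {
  if (inherits(specs, "profile_spec")) specs <- list(specs)
  ids <- vapply(specs, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene ids in specs")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vals <- t(vapply(specs, function(s) {
    x <- .eval_spec(s, time_points_h)
    if (s$noise_sd > 0) x <- x + stats::rnorm(length(x), 0, s$noise_sd)
    pmax(x, 0)
  }, numeric(length(time_points_h))))
  rownames(vals) <- ids
  expression_series(vals, time_points_h)
}

#' Profile specifications of the packaged diurnal fixture
#'
#' One specification per measured starch-pathway gene (29 of 43; the 14
#' genes without microarray data are omitted so downstream code exercises
#' the 0.01 imputation floor). Shapes follow the qualitative phase classes
#' of the measured transcripts: phosphoglucoisomerase/phosphoglucomutase
#' peak in the first hours of light and decay to an early-night minimum;
#' the AGPase small subunit and GBSSI rise through the day to a peak just
#' before lights-off; SSI/SSIII and SBEII show late-night/early-morning
#' double peaks; SBEI peaks mid-day; the degradation cluster (two
#' alpha-amylases, one beta-amylase, pullulanase, starch phosphorylase,
#' DPE1 and the maltose transporter MEX1) peaks at dusk and reaches its
#' minimum just before dawn (MEX1 bottoms out exactly at ZT21); ISA3 falls
#' through the day and rises at night; GWD follows an approximate 12 h
#' rhythm peaking mid-day and mid-night.
#'
#' @return List of `profile_spec`.
#' @export
fixture_profile_specs <- function() {
  dusk <- function(g) profile_spec(g, "double_peak", peak_time_h = 12,
                                   width_h = 8, amplitude = 1,
                                   peak2_time_h = 2, amplitude2 = 0.35,
                                   width2_h = 4)
  dpk <- function(g) profile_spec(g, "double_peak", peak_time_h = 21,
                                  width_h = 7, amplitude = 1,
                                  peak2_time_h = 3, amplitude2 = 1,
                                  width2_h = 7)
  list(
    # gluconeogenic entry
    profile_spec("Ot11g02980", "single_peak", peak_time_h = 2,  width_h = 13),   # GPI
    profile_spec("Ot15g02630", "single_peak", peak_time_h = 2,  width_h = 13),   # PGM
    profile_spec("Ot09g00080", "single_peak", peak_time_h = 4,  width_h = 7.5),  # TPI
    profile_spec("Ot01g03020", "single_peak", peak_time_h = 17, width_h = 7),    # fbaI
    profile_spec("Ot03g00610", "single_peak", peak_time_h = 19, width_h = 7),    # fbaI
    profile_spec("Ot10g01490", "single_peak", peak_time_h = 6,  width_h = 7.5),  # fbaII
    profile_spec("Ot03g00330", "single_peak", peak_time_h = 6,  width_h = 7.5),  # FBPase
    profile_spec("Ot14g01140", "single_peak", peak_time_h = 9,  width_h = 7.5),  # FBPase
    # synthesis
    profile_spec("Ot07g02930", "double_peak", peak_time_h = 11, width_h = 8,
                 peak2_time_h = 6.5, amplitude2 = 0.35, width2_h = 3),           # AGPase small subunit (steep day rise, pre-dusk peak)
    profile_spec("Ot06g03200", "single_peak", peak_time_h = 11, width_h = 9),    # GBSSI
    dpk("Ot13g01230"),                                                           # SSI
    dpk("Ot16g01560"),                                                           # SSIII-A
    dpk("Ot13g01250"),                                                           # SSIII-B
    profile_spec("Ot16g02790", "step_at_transition", peak_time_h = 12),          # SSII
    dpk("Ot03g00840"),                                                           # SBEII
    profile_spec("Ot04g04110", "single_peak", peak_time_h = 6, width_h = 7.5),   # SBEI
    dpk("Ot14g02550"),                                                           # ISA1
    # degradation (dusk cluster)
    dusk("Ot07g02010"),                                                          # alpha-amylase (granule)
    dusk("Ot10g00260"),                                                          # alpha-amylase
    dusk("Ot02g06980"),                                                          # beta-amylase
    dusk("Ot03g03190"),                                                          # beta-amylase Bamy2
    dusk("Ot01g03030"),                                                          # pullulanase
    dusk("Ot04g02110"),                                                          # starch phosphorylase
    dusk("Ot02g05750"),                                                          # DPE1
    dusk("Ot09g03160"),                                                          # MEX1 (exactly 0 at ZT21)
    profile_spec("Ot16g00380", "single_peak", peak_time_h = 9, width_h = 8),     # alpha-amylase pair
    profile_spec("Ot02g05490", "single_peak", peak_time_h = 9, width_h = 8),
    profile_spec("Ot12g00310", "single_peak", peak_time_h = 19, width_h = 12),   # ISA3
    # GWD: ~12 h rhythm, peaks mid-day and mid-night, deeper trough at dawn
    profile_spec("Ot13g01510", "double_peak", peak_time_h = 7, width_h = 8,
                 peak2_time_h = 17.5, width2_h = 8)
  )
}

#' Packaged diurnal expression fixture
#'
#' Generates the 29-gene synthetic expression series on the canonical
#' 3 h grid (ZT0-ZT24) from [fixture_profile_specs()].
#'
#' @param seed RNG seed.
#' @param noise_sd Gaussian noise SD applied to every profile (default
#'   0.05, i.e. 5% of the unit amplitude).
#' @return An `expression_series` with 29 genes and 9 time points.
#' @export
diel_expression_fixture <- function(seed = 1L, noise_sd = 0.05) {
  specs <- lapply(fixture_profile_specs(), function(s) {
    s$noise_sd <- noise_sd
    s
  })
  generate_profiles(specs, seq(0, 24, by = 3), seed = seed)
}
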