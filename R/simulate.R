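#' Default per-class phenology parameter distributions
#'
#' Population means and spreads of the double-sigmoid parameters per class,
#' chosen to mimic Corn Belt seasonality: corn greens up around mid-June
#' (`D_i` ~ 160) and senesces in early September, soybean runs about 12 days
#' later with a slightly lower amplitude, and "other" (grass, forest, water,
#' towns pooled) has a weak, broad cycle with low amplitude.
#'
#' @return Tibble with one row per class: mean and sd of `V_b`, `V_a`, `p`,
#'   `D_i`, `q`, `D_d`.
#' @export
default_pheno_params <- function() {
  tibble::tribble(
    ~class,     ~V_b, ~V_b_sd, ~V_a, ~V_a_sd,   ~p,  ~p_sd, ~D_i, ~D_i_sd,    ~q,  ~q_sd, ~D_d, ~D_d_sd,
    "corn",     0.12,   0.015, 0.55,    0.05, 0.120, 0.012,  160,       4, 0.100,  0.010,  252,       5,
    "soybean",  0.12,   0.015, 0.50,    0.05, 0.105, 0.012,  172,       4, 0.115,  0.010,  264,       5,
    "other",    0.18,   0.020, 0.10,    0.03, 0.045, 0.008,  130,      12, 0.035,  0.006,  290,      15
  )
}

#' Default per-class band archetypes
#'
#' Reflectance of each band is modeled as `base + slope * g(t)` with `g` the
#' normalized greenness of the class trajectory (0 off-season, 1 at peak);
#' the NIR band (b2) is not listed because it is solved from the EVI
#' trajectory. Corn and soybean are given distinct SWIR1-green behavior
#' (corn's SWIR1 drops much more at peak) so the VI64/DIF64 contrast that
#' separates the two crops in practice is present in the synthetic scenes.
#'
#' @return Tibble with columns `class`, `band`, `base`, `slope`.
#' @export
default_band_archetypes <- function() {
  tibble::tribble(
    ~class,     ~band, ~base, ~slope,
    "corn",     "b1",  0.090, -0.055,
    "corn",     "b3",  0.045, -0.020,
    "corn",     "b4",  0.085, -0.010,
    "corn",     "b5",  0.250,  0.100,
    "corn",     "b6",  0.280, -0.160,
    "corn",     "b7",  0.170, -0.090,
    "soybean",  "b1",  0.090, -0.050,
    "soybean",  "b3",  0.045, -0.020,
    "soybean",  "b4",  0.095,  0.015,
    "soybean",  "b5",  0.250,  0.110,
    "soybean",  "b6",  0.270, -0.050,
    "soybean",  "b7",  0.160, -0.050,
    "other",    "b1",  0.100, -0.020,
    "other",    "b3",  0.050, -0.010,
    "other",    "b4",  0.090,  0.000,
    "other",    "b5",  0.230,  0.050,
    "other",    "b6",  0.260, -0.040,
    "other",    "b7",  0.160, -0.030
  )
}

#' Default crop-progress stage definitions
#'
#' Simulator convention linking reported stages to phenology: each stage's
#' population mean date is an anchor metric of the class trajectory
#' (`D_1` emergence, `D_peak` peak growth, `D_4` end of senescence) plus an
#' offset in days. Corn reports 7 stages and soybean 6, pooled into one
#' 13-item progress vector per state-year.
#'
#' @return Tibble with columns `crop`, `stage`, `anchor`, `offset`.
#' @export
default_stage_table <- function() {
  tibble::tribble(
    ~crop,      ~stage,            ~anchor,  ~offset,
    "corn",     "planted",         "D_1",    -12,
    "corn",     "emerged",         "D_1",      0,
    "corn",     "silking",         "D_peak",   0,
    "corn",     "dough",           "D_peak",  18,
    "corn",     "dented",          "D_peak",  30,
    "corn",     "mature",          "D_4",      0,
    "corn",     "harvested",       "D_4",     18,
    "soybean",  "planted",         "D_1",    -12,
    "soybean",  "emerged",         "D_1",      0,
    "soybean",  "blooming",        "D_peak",  -5,
    "soybean",  "setting_pods",    "D_peak",  10,
    "soybean",  "dropping_leaves", "D_4",     -8,
    "soybean",  "harvested",       "D_4",     15
  )
}

#' Simulation configuration
#'
#' Defines the study conditions of a synthetic cross-year experiment: a fine
#' crop-label grid (emulating a 30 m label raster), coarse pixels of
#' `factor x factor` fine cells (emulating ~500 m composites), a county
#' partition of the coarse grid, three years with uniform phenology shifts,
#' and the noise/missingness of the reflectance record.
#'
#' Defaults: a 512 x 512 fine grid aggregated by 16 (32 x 32 coarse pixels)
#' over an 8 x 8 county grid; rectangular fields with 8-24-cell edges
#' (240-720 m, typical Corn Belt fields); landscape proportions 40% corn,
#' 40% soybean, 20% other with a +/-15-point west-east corn/soybean gradient
#' providing county-scale spatial structure; years 2012-2014 with phenology
#' shifts (0, +15, +5) days so the most recent (mapping) year's prior year is
#' the dissimilar one; EVI noise sd 0.02 and a 5% rate of bad composites.
#'
#' @param seed Base random seed; every stochastic step derives from it.
#' @param fine_dim Fine-grid dimensions (rows, cols), divisible by `factor`.
#' @param factor Aggregation block size in fine cells.
#' @param county_grid Counties along (rows, cols) of the coarse grid.
#' @param field_size Range of field edge lengths in fine cells.
#' @param prop Landscape class proportions (corn, soybean, other), summing
#'   to 1.
#' @param prop_gradient Half-range of the west-east linear corn/soybean
#'   proportion gradient.
#' @param years Simulated years.
#' @param shifts Uniform phenology shift per year, in days.
#' @param state State code attached to progress records.
#' @param evi_noise_sd Gaussian noise sd on the EVI trajectory.
#' @param band_noise_sd Gaussian noise sd on band reflectance.
#' @param missing_rate Probability that a composite is flagged bad.
#' @param stage_sd Field-to-field spread (days) of stage dates, setting the
#'   steepness of weekly progress curves.
#' @param stage_jitter_sd Year-to-year jitter (days) on stage mean dates
#'   beyond the uniform shift.
#' @param pheno,bands,stages Class parameter tables; see
#'   [default_pheno_params()], [default_band_archetypes()],
#'   [default_stage_table()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       fine_dim = c(512L, 512L),
                       factor = 16L,
                       county_grid = c(8L, 8L),
                       field_size = c(8L, 24L),
                       prop = c(corn = 0.4, soybean = 0.4, other = 0.2),
                       prop_gradient = 0.15,
                       years = c(2012L, 2013L, 2014L),
                       shifts = c(0, 15, 5),
                       state = "IA",
                       evi_noise_sd = 0.02,
                       band_noise_sd = 0.005,
                       missing_rate = 0.05,
                       stage_sd = 7,
                       stage_jitter_sd = 0.75,
                       pheno = default_pheno_params(),
                       bands = default_band_archetypes(),
                       stages = default_stage_table()) {
  stopifnot(length(fine_dim) == 2, length(county_grid) == 2,
            length(field_size) == 2, field_size[1] >= 1,
            field_size[2] >= field_size[1],
            length(years) == length(shifts),
            evi_noise_sd >= 0, band_noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  if (abs(sum(prop) - 1) > 1e-8) abort("class proportions must sum to 1")
  if (any(fine_dim %% factor != 0)) {
    abort("fine_dim must be divisible by the aggregation factor")
  }
  coarse <- fine_dim %/% factor
  if (any(coarse %% county_grid != 0)) {
    abort("coarse grid must be divisible by county_grid")
  }
  structure(
    list(seed = as.integer(seed), fine_dim = as.integer(fine_dim),
         factor = as.integer(factor), county_grid = as.integer(county_grid),
         field_size = as.integer(field_size), prop = prop,
         prop_gradient = prop_gradient, years = as.integer(years),
         shifts = shifts, state = state,
         evi_noise_sd = evi_noise_sd, band_noise_sd = band_noise_sd,
         missing_rate = missing_rate, stage_sd = stage_sd,
         stage_jitter_sd = stage_jitter_sd,
         pheno = pheno, bands = bands, stages = stages),
    class = "sim_config"
  )
}

.year_shift <- function(config, year) {
  i <- match(year, config$years)
  if (is.na(i)) abort(sprintf("year %s is not in the configuration", year))
  config$shifts[i]
}

# deterministic sub-seed per (year, purpose); kept well below 2^31
.sub_seed <- function(config, year, salt) {
  (config$seed + salt * 1000003L + (year %% 1009L) * 7919L) %% 2000000011L
}

# random field-edge breaks covering n cells; returns the field index per cell
.field_index <- function(n, field_size) {
  sizes <- seq(field_size[1], field_size[2])
  lens <- integer(0)
  total <- 0L
  while (total < n) {
    l <- sizes[sample.int(length(sizes), 1L)]
    lens <- c(lens, l)
    total <- total + l
  }
  lens[length(lens)] <- lens[length(lens)] - (total - n)
  rep(seq_along(lens), lens)
}

#' Simulate a fine-resolution crop-label landscape
#'
#' Tiles the fine grid with rectangular fields (random edge lengths within
#' `field_size`) and assigns each field a class. Corn and soybean
#' probabilities vary linearly west to east by `prop_gradient` (opposite
#' signs, so the landscape total stays at the configured proportions) to give
#' counties distinct crop intensities. Deterministic given the configuration
#' seed and year.
#'
#' @param config A [sim_config()].
#' @param year Simulated year (each year gets an independent rotation).
#' @return Integer matrix of class codes (0 other, 1 corn, 5 soybean) with
#'   attribute `year`.
#' @export
simulate_landscape <- function(config, year = config$years[1]) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(.sub_seed(config, year, 1L), {
    nr <- config$fine_dim[1]
    nc <- config$fine_dim[2]
    ri <- .field_index(nr, config$field_size)
    ci <- .field_index(nc, config$field_size)
    nfr <- max(ri)
    nfc <- max(ci)
    # column fraction of each field column drives the corn/soybean gradient
    col_centers <- tapply(seq_len(nc), ci, mean) / nc
    delta <- config$prop_gradient * 2 * (col_centers - 0.5)
    pc <- pmax(config$prop["corn"] + delta, 0)
    ps <- pmax(config$prop["soybean"] - delta, 0)
    po <- pmax(1 - pc - ps, 0)
    tot <- pc + ps + po
    pc <- pc / tot
    ps <- ps / tot
    u <- matrix(runif(nfr * nfc), nfr, nfc)
    pcm <- matrix(pc, nfr, nfc, byrow = TRUE)
    psm <- matrix(ps, nfr, nfc, byrow = TRUE)
    codes <- matrix(0L, nfr, nfc)
    codes[u < pcm] <- 1L
    codes[u >= pcm & u < pcm + psm] <- 5L
    fine <- codes[ri, ci, drop = FALSE]
    attr(fine, "year") <- year
    fine
  })
}

# draw per-pixel double-sigmoid parameters for one class, clamped inside the
# fitting bounds, with the year's uniform date shift applied
.draw_class_params <- function(config, class, n, shift) {
  row <- config$pheno[config$pheno$class == class, , drop = FALSE]
  if (nrow(row) != 1) abort(sprintf("unknown class '%s'", class))
  V_b <- pmin(pmax(rnorm(n, row$V_b, row$V_b_sd), -0.1), 0.5)
  V_a <- pmin(pmax(rnorm(n, row$V_a, row$V_a_sd), 0.02), 1.1)
  p <- pmin(pmax(rnorm(n, row$p, row$p_sd), 0.02), 0.6)
  q <- pmin(pmax(rnorm(n, row$q, row$q_sd), 0.02), 0.6)
  D_i <- pmin(pmax(rnorm(n, row$D_i, row$D_i_sd) + shift, 40), 300)
  D_d <- pmin(pmax(rnorm(n, row$D_d, row$D_d_sd) + shift, D_i + 20), 350)
  list(V_b = V_b, V_a = V_a, p = p, D_i = D_i, q = q, D_d = D_d)
}

# core band synthesis: weighted class mixture of EVI trajectories and band
# archetypes; NIR (b2) is solved from the noisy EVI so the computed index
# reproduces the injected trajectory
.synth_series <- function(config, W, params_by_class, noisy = TRUE) {
  t <- doy_composites()
  nt <- length(t)
  npix <- nrow(W)
  Tm <- matrix(t, npix, nt, byrow = TRUE)
  E_mix <- matrix(0, npix, nt)
  G <- list()
  for (k in seq_along(.crop_classes)) {
    cls <- .crop_classes[k]
    pp <- params_by_class[[cls]]
    Ek <- pp$V_b + pp$V_a *
      (stats::plogis(pp$p * (Tm - pp$D_i)) - stats::plogis(pp$q * (Tm - pp$D_d)))
    G[[cls]] <- pmin(pmax((Ek - pp$V_b) / pmax(pp$V_a, 0.02), 0), 1.2)
    E_mix <- E_mix + W[, k] * Ek
  }
  e <- E_mix
  if (noisy && config$evi_noise_sd > 0) {
    e <- e + matrix(rnorm(npix * nt, 0, config$evi_noise_sd), npix, nt)
  }
  e <- pmin(pmax(e, -0.3), 1.2)
  bands <- list()
  for (b in c("b1", "b3", "b4", "b5", "b6", "b7")) {
    Bb <- matrix(0, npix, nt)
    for (k in seq_along(.crop_classes)) {
      cls <- .crop_classes[k]
      arc <- config$bands[config$bands$class == cls & config$bands$band == b, ]
      Bb <- Bb + W[, k] * (arc$base + arc$slope * G[[cls]])
    }
    if (noisy && config$band_noise_sd > 0) {
      Bb <- Bb + matrix(rnorm(npix * nt, 0, config$band_noise_sd), npix, nt)
    }
    bands[[b]] <- pmin(pmax(Bb, 0.005), 0.98)
  }
  bands$b2 <- pmin(pmax(
    (2.5 * bands$b1 + e * (6 * bands$b1 - 7.5 * bands$b3 + 1)) / (2.5 - e),
    0.005), 0.98)
  good <- matrix(TRUE, npix, nt)
  if (noisy && config$missing_rate > 0) {
    bad <- matrix(runif(npix * nt) < config$missing_rate, npix, nt)
    # cloud-like contamination on flagged composites
    bands$b1[bad] <- pmin(bands$b1[bad] + 0.30, 0.98)
    bands$b3[bad] <- pmin(bands$b3[bad] + 0.25, 0.98)
    bands$b2[bad] <- pmax(bands$b2[bad] - 0.20, 0.02)
    good[bad] <- FALSE
  }
  list(doy = t, bands = bands, good = good, evi_true = E_mix)
}

#' Simulate one pixel-year of reflectance
#'
#' Generates a single-class composite series: the EVI trajectory is a
#' double sigmoid with the class's (or the supplied) parameters plus Gaussian
#' noise, band reflectances follow the class archetypes modulated by
#' greenness, the NIR band is solved so that the computed EVI reproduces the
#' trajectory, and composites are flagged bad (with cloud-like contamination)
#' at the configured missing rate.
#'
#' @param config A [sim_config()].
#' @param class `"corn"`, `"soybean"` or `"other"`.
#' @param shift Uniform date shift in days.
#' @param params Optional named vector/list of double-sigmoid parameters
#'   (`V_b`, `V_a`, `p`, `D_i`, `q`, `D_d`) overriding the class draw.
#' @param seed Seed for this pixel (defaults to the configuration seed).
#' @return Tibble with columns `doy`, `b1`..`b7`, `good`; attributes
#'   `params` (the injected parameters) and `evi_true` (the noise-free
#'   trajectory).
#' @export
simulate_pixel_series <- function(config, class = "corn", shift = 0,
                                  params = NULL, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  class <- match.arg(class, .crop_classes)
  withr::with_seed(seed, {
    pp <- if (is.null(params)) {
      lapply(.draw_class_params(config, class, 1L, shift), unname)
    } else {
      as.list(params[c("V_b", "V_a", "p", "D_i", "q", "D_d")])
    }
    W <- matrix(0, 1, 3)
    W[1, match(class, .crop_classes)] <- 1
    by_class <- setNames(rep(list(pp), 3), .crop_classes)
    syn <- .synth_series(config, W, by_class)
    out <- tibble::tibble(doy = syn$doy)
    for (b in .band_cols) out[[b]] <- as.numeric(syn$bands[[b]][1, ])
    out$good <- as.logical(syn$good[1, ])
    attr(out, "params") <- unlist(pp)
    attr(out, "evi_true") <- as.numeric(syn$evi_true[1, ])
    out
  })
}

#' County zone raster for a configuration
#'
#' Partitions the coarse grid into the configured county grid; county ids
#' run row-major from the northwest corner.
#'
#' @param config A [sim_config()].
#' @return Integer matrix of county ids at coarse-pixel resolution.
#' @export
county_zones <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  coarse <- config$fine_dim %/% config$factor
  per <- coarse %/% config$county_grid
  rid <- (seq_len(coarse[1]) - 1L) %/% per[1]
  cid <- (seq_len(coarse[2]) - 1L) %/% per[2]
  outer(rid, cid, function(r, c) r * config$county_grid[2] + c + 1L)
}

#' Simulate one state-year scene
#'
#' Generates the complete inputs of one state-year: the fine label raster,
#' its exact coverage aggregation (the fuzzy truth), the county zone raster,
#' and the coarse-pixel reflectance series. Each coarse pixel's EVI is the
#' coverage-weighted mixture of per-pixel class trajectories (parameters
#' drawn per pixel from the class distributions, shifted by the year's
#' phenology shift), so the sub-pixel composition is expressed in the
#' spectral record exactly as mixed coarse pixels express it in reality.
#'
#' @param config A [sim_config()].
#' @param year One of `config$years`.
#' @return A `crop_scene` list: `year`, `shift`, `state`, `fine`, `coverage`,
#'   `zones`, `series`, `factor`.
#' @export
simulate_scene <- function(config, year = config$years[1]) {
  stopifnot(inherits(config, "sim_config"))
  shift <- .year_shift(config, year)
  fine <- simulate_landscape(config, year)
  coverage <- aggregate_coverage(fine, config$factor)
  zones <- county_zones(config)
  series <- withr::with_seed(.sub_seed(config, year, 2L), {
    W <- as.matrix(coverage[, c("corn", "soybean", "other")]) / 100
    npix <- nrow(W)
    by_class <- setNames(lapply(.crop_classes, function(cls) {
      .draw_class_params(config, cls, npix, shift)
    }), .crop_classes)
    syn <- .synth_series(config, W, by_class)
    nt <- length(syn$doy)
    out <- tibble::tibble(
      pixel = rep(coverage$pixel, times = nt),
      row = rep(coverage$row, times = nt),
      col = rep(coverage$col, times = nt),
      doy = rep(syn$doy, each = npix)
    )
    for (b in .band_cols) out[[b]] <- as.numeric(syn$bands[[b]])
    out$good <- as.logical(syn$good)
    out[order(out$pixel, out$doy), , drop = FALSE]
  })
  structure(
    list(year = year, shift = shift, state = config$state, fine = fine,
         coverage = coverage, zones = zones, series = series,
         factor = config$factor),
    class = "crop_scene"
  )
}

#' @export
print.crop_scene <- function(x, ...) {
  cat(sprintf("<crop_scene> year %d (shift %+g d), state %s: %d x %d fine, %d coarse pixels\n",
              x$year, x$shift, x$state, nrow(x$fine), ncol(x$fine),
              nrow(x$coverage)))
  invisible(x)
}

# population anchor dates (D_1, D_peak, D_4) of a class from its parameter
# means; D_peak by grid argmax of the mean trajectory
.class_anchors <- function(config, class) {
  row <- config$pheno[config$pheno$class == class, , drop = FALSE]
  k <- .sigmoid_k
  grid <- seq(1, 365, by = 0.25)
  curve <- double_sigmoid(grid, row$V_b, row$V_a, row$p, row$D_i, row$q, row$D_d)
  c(D_1 = row$D_i - k / row$p,
    D_peak = grid[which.max(curve)],
    D_4 = row$D_d + k / row$q)
}

#' Simulate weekly crop-progress tables
#'
#' Emulates the weekly report: for each year, crop and stage, the cumulative
#' percent complete at each week's end is the Gaussian CDF of the stage-date
#' population (anchor date + offset + the year's phenology shift + a small
#' year-specific jitter; spread `stage_sd`), rounded to whole percent as
#' published. Cumulative percentages are non-decreasing by construction.
#'
#' @param config A [sim_config()].
#' @param years Years to report (default all configured years).
#' @return Tibble with columns `state`, `year`, `crop`, `stage`,
#'   `week_ending_doy`, `percent`.
#' @export
simulate_progress_table <- function(config, years = config$years) {
  stopifnot(inherits(config, "sim_config"))
  weeks <- seq(92, 337, by = 7)
  purrr::map_dfr(years, function(year) {
    shift <- .year_shift(config, year)
    withr::with_seed(.sub_seed(config, year, 3L), {
      purrr::map_dfr(unique(config$stages$crop), function(cr) {
        anchors <- .class_anchors(config, cr)
        st <- config$stages[config$stages$crop == cr, , drop = FALSE]
        purrr::map_dfr(seq_len(nrow(st)), function(i) {
          mu <- anchors[[st$anchor[i]]] + st$offset[i] + shift +
            rnorm(1, 0, config$stage_jitter_sd)
          tibble::tibble(
            state = config$state, year = year, crop = cr,
            stage = st$stage[i], week_ending_doy = weeks,
            percent = round(100 * pnorm(weeks, mu, config$stage_sd))
          )
        })
      })
    })
  })
}

#' Simulate a complete cross-year experiment
#'
#' One scene per configured year plus the pooled weekly progress table: the
#' full input set of the cross-year workflow.
#'
#' @param config A [sim_config()].
#' @return A `crop_experiment` list: `config`, `scenes` (named by year),
#'   `progress`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  scenes <- lapply(config$years, function(y) simulate_scene(config, y))
  names(scenes) <- as.character(config$years)
  structure(
    list(config = config, scenes = scenes,
         progress = simulate_progress_table(config)),
    class = "crop_experiment"
  )
}

#' @export
print.crop_experiment <- function(x, ...) {
  cat(sprintf("<crop_experiment> state %s, years %s (shifts %s)\n",
              x$config$state, paste(x$config$years, collapse = ", "),
              paste(sprintf("%+g", x$config$shifts), collapse = ", ")))
  invisible(x)
}
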