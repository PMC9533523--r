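# Synthetic cohorts: tissue maps, IHC-like images and detections, survival.
#
# The generator emulates the statistical structure the analysis assumes:
# a stroma fraction distributed around the 50% cutoff, a latent lymphocyte
# infiltration level driving both the LYM probability in stroma and the CD3
# density, group-mean CD3 densities, and exponential group survival pinned
# to 5-year rates. It makes no attempt at photorealistic histology.

# sample() without the scalar-x surprise
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render colors for the nine tissue classes
#'
#' Fixed, mutually distinct RGB colors (unit scale) used by [render_rgb()]
#' and inverted exactly by the mock classifier's color lookup.
#'
#' @format 9 x 3 numeric matrix, rows named by [TISSUE_CLASSES].
#' @export
CLASS_COLORS <- matrix(c(
  1.0, 1.0, 0.4,   # ADI  pale yellow
  1.0, 1.0, 1.0,   # BAC  white
  0.4, 0.4, 0.4,   # DEB  gray
  0.2, 0.2, 0.8,   # LYM  blue
  0.6, 1.0, 1.0,   # MUC  cyan
  0.8, 0.4, 0.2,   # MUS  brown
  0.4, 0.8, 0.4,   # NOR  green
  1.0, 0.6, 0.8,   # STR  pink
  0.6, 0.2, 0.6),  # TUM  purple
  nrow = 9, byrow = TRUE,
  dimnames = list(c("ADI", "BAC", "DEB", "LYM", "MUC", "MUS", "NOR", "STR", "TUM"),
                  c("R", "G", "B")))

#' Simulation configuration
#'
#' Collects every generator parameter with defaults set to the conditions the
#' analysis is validated against: CD3 group-mean densities of 844, 1088, 1246
#' and 1708 cells/mm^2 for immune scores 1-4, and 5-year overall survival of
#' 58.2% and 87.4% for scores 1 and 4. The score-2 and score-3 survival
#' defaults (69.2%, 77.0%) are implied by the score-group hazard ratios under
#' the exponential model (see the methods vignette). Group hazards are
#' `lambda_g = -log(S5_g) / 5`.
#'
#' @param n_patients Cohort size.
#' @param tsr_mean,tsr_sd Normal stroma-fraction distribution, clipped to
#'   `[0.02, 0.98]`; defaults 0.45 / 0.12 put roughly two thirds of patients
#'   below the 50% cutoff.
#' @param theta_mean,theta_conc Beta distribution of the latent infiltration
#'   level theta (mean, concentration); defaults 0.15 / 12.
#' @param dirichlet_alpha Patch-probability concentration (noise); `Inf`
#'   means noise-free maps.
#' @param grid_dims Map grid rows/cols, default `c(30, 30)`.
#' @param density_means Length-4 CD3 density means (cells/mm^2) by immune
#'   score group.
#' @param density_sd_frac Per-patient density sd as a fraction of the group
#'   mean, default 0.10.
#' @param five_year_survival Length-4 group 5-year survival probabilities.
#' @param censor_horizon Administrative censoring time in years, default 10.
#' @param dropout_rate Fraction of patients with an additional uniform(0,
#'   `censor_horizon`) dropout time, default 0.2.
#' @param stage_probs,sex_prob_male,grade_prob_high,cea_prob_abnormal,
#'   location_prob_rectum,age_mean,age_sd Covariate distributions.
#' @param stage_score_assoc In `[0, 1]`: 0 draws stage independently of the
#'   score; larger values shift low-score patients toward stage III.
#' @param seed Integer seed; fully determines the cohort.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 100L,
                       tsr_mean = 0.45, tsr_sd = 0.12,
                       theta_mean = 0.15, theta_conc = 12,
                       dirichlet_alpha = Inf,
                       grid_dims = c(30L, 30L),
                       density_means = c(844, 1088, 1246, 1708),
                       density_sd_frac = 0.10,
                       five_year_survival = c(0.582, 0.692, 0.770, 0.874),
                       censor_horizon = 10,
                       dropout_rate = 0.2,
                       stage_probs = c(I = 0.2, II = 0.4, III = 0.4),
                       sex_prob_male = 0.55,
                       grade_prob_high = 0.2,
                       cea_prob_abnormal = 0.3,
                       location_prob_rectum = 0.5,
                       age_mean = 62, age_sd = 12,
                       stage_score_assoc = 0,
                       seed = 1L) {
  if (any(five_year_survival <= 0 | five_year_survival >= 1))
    stop("five_year_survival values must lie in (0, 1)")
  if (length(density_means) != 4L || length(five_year_survival) != 4L)
    stop("density_means and five_year_survival must have one value per score 1..4")
  if (tsr_mean < 0 || tsr_mean > 1 || theta_mean <= 0 || theta_mean >= 1)
    stop("tsr_mean and theta_mean must lie in [0, 1]")
  if (dropout_rate < 0 || dropout_rate > 1) stop("dropout_rate must lie in [0, 1]")
  structure(list(
    n_patients = as.integer(n_patients), tsr_mean = tsr_mean, tsr_sd = tsr_sd,
    theta_mean = theta_mean, theta_conc = theta_conc,
    dirichlet_alpha = dirichlet_alpha, grid_dims = as.integer(grid_dims),
    density_means = density_means, density_sd_frac = density_sd_frac,
    five_year_survival = five_year_survival,
    lambda = -log(five_year_survival) / 5,
    censor_horizon = censor_horizon, dropout_rate = dropout_rate,
    stage_probs = stage_probs, sex_prob_male = sex_prob_male,
    grade_prob_high = grade_prob_high, cea_prob_abnormal = cea_prob_abnormal,
    location_prob_rectum = location_prob_rectum,
    age_mean = age_mean, age_sd = age_sd,
    stage_score_assoc = stage_score_assoc, seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a pixel-level tissue label image
#'
#' Builds a class-coded label raster emulating the tissue layout a patch
#' classifier would segment: a tumor-epithelium canvas with planted stroma
#' blobs (grown at patch resolution from random seeds, so the patch-level
#' stroma fraction hits the target within 0.02), lymphocyte-aggregate disks
#' planted inside stroma with pixel coverage increasing in `theta`, and a
#' border ring of normal mucosa / adipose / background patches.
#'
#' @param target_tsr Target stroma fraction of the tumor bed, in [0, 1].
#' @param theta Latent infiltration level in [0, 1]; 0 plants no LYM pixels.
#' @param dims Image height/width in pixels, default `c(256, 256)`.
#' @param patch_px Synthetic patch side in pixels, default 16 (a scaled-down
#'   stand-in for 224 px patches so fixtures stay small).
#' @param seed Optional integer seed.
#' @param max_iter Blob-growth iteration bound before declaring the target
#'   infeasible.
#' @return Integer matrix of class indices into [TISSUE_CLASSES].
#' @export
simulate_label_image <- function(target_tsr, theta, dims = c(256L, 256L),
                                 patch_px = 16L, seed = NULL, max_iter = 10000L) {
  if (target_tsr < 0 || target_tsr > 1) stop("target_tsr must lie in [0, 1]")
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  pr <- dims[1] %/% patch_px; pc <- dims[2] %/% patch_px
  if (pr < 3L || pc < 3L)
    stop("infeasible target at given dims: need at least a 3 x 3 patch grid")
  with_seed(seed, {
    # patch-level plan: border ring NOR/ADI/BAC, interior tumor bed
    plan <- matrix(class_index("TUM"), pr, pc)
    border_classes <- class_index(c("NOR", "ADI", "BAC"))
    edge <- row(plan) == 1 | row(plan) == pr | col(plan) == 1 | col(plan) == pc
    plan[edge] <- sample(border_classes, sum(edge), replace = TRUE)
    interior <- which(!edge)
    n_bed <- length(interior)
    n_str <- round(target_tsr * n_bed)
    if (abs(n_str / n_bed - target_tsr) > 0.02)
      stop("infeasible target at given dims: grid too coarse for target_tsr")
    if (n_str > 0L) {
      # region growth: random seeds, then accrete random neighbors -> blobs
      is_str <- rep(FALSE, pr * pc)
      n_seeds <- max(1L, round(n_str / 12))
      frontier <- resample(interior, min(n_seeds, n_str))
      is_str[frontier] <- TRUE
      placed <- length(frontier)
      it <- 0L
      while (placed < n_str) {
        it <- it + 1L
        if (it > max_iter) stop("infeasible target at given dims: blob growth did not converge")
        cur <- which(is_str)
        r <- ((cur - 1L) %% pr) + 1L; c <- ((cur - 1L) %/% pr) + 1L
        cand <- unique(c(
          (c - 1L) * pr + pmax(r - 1L, 1L), (c - 1L) * pr + pmin(r + 1L, pr),
          (pmax(c - 1L, 1L) - 1L) * pr + r, (pmin(c + 1L, pc) - 1L) * pr + r))
        cand <- setdiff(intersect(cand, interior), cur)
        if (!length(cand)) cand <- setdiff(interior, cur)
        take <- resample(cand, min(length(cand), n_str - placed))
        is_str[take] <- TRUE
        placed <- placed + length(take)
      }
      plan[is_str] <- class_index("STR")
    }
    # paint pixels from the patch plan
    img <- matrix(0L, pr * patch_px, pc * patch_px)
    for (r in seq_len(pr)) for (c in seq_len(pc)) {
      img[(r - 1L) * patch_px + seq_len(patch_px),
          (c - 1L) * patch_px + seq_len(patch_px)] <- plan[r, c]
    }
    # LYM aggregates: small disks centered in stroma, coverage ~ 0.4 * theta
    if (theta > 0 && any(plan == class_index("STR"))) {
      str_px <- which(img == class_index("STR"))
      target_cov <- 0.4 * theta * length(str_px)
      radius <- max(2L, patch_px %/% 5L)
      H <- nrow(img); W <- ncol(img)
      covered <- 0L; it <- 0L
      while (covered < target_cov) {
        it <- it + 1L
        if (it > max_iter) break
        ctr <- resample(str_px, 1L)
        cr <- ((ctr - 1L) %% H) + 1L; cc <- ((ctr - 1L) %/% H) + 1L
        rr <- pmax(1L, cr - radius):pmin(H, cr + radius)
        cc2 <- pmax(1L, cc - radius):pmin(W, cc + radius)
        blk <- as.matrix(expand.grid(r = rr, c = cc2))
        blk <- blk[(blk[, 1] - cr)^2 + (blk[, 2] - cc)^2 <= radius^2, , drop = FALSE]
        lin <- (blk[, 2] - 1L) * H + blk[, 1]
        lin <- lin[img[lin] == class_index("STR")]
        img[lin] <- class_index("LYM")
        covered <- covered + length(lin)
      }
    }
    img
  })
}

#' Render a label raster to an RGB image
#'
#' Each tissue class maps to its fixed [CLASS_COLORS] color.
#'
#' @param labels Integer matrix of class indices.
#' @return Numeric array `H x W x 3` in [0, 1].
#' @export
render_rgb <- function(labels) {
  if (anyNA(labels) || any(labels < 1L) || any(labels > 9L))
    stop("labels must be class indices in 1..9")
  H <- nrow(labels); W <- ncol(labels)
  array(CLASS_COLORS[cbind(as.vector(labels),
                           rep(1:3, each = H * W))], c(H, W, 3))
}

#' Mock color-lookup patch classifier
#'
#' Returns a classifier closure satisfying the [classify_patches()] contract:
#' each pixel of a rendered patch is matched (exactly) back to its class
#' color, per-class pixel fractions are computed, and the fraction vector is
#' perturbed with Dirichlet(`alpha` * fractions) noise. `alpha = Inf` returns
#' the exact fractions; classes absent from the patch keep probability zero.
#'
#' @param alpha Dirichlet concentration, default `Inf` (noise-free).
#' @return Function patch (H x W x 3 array) -> numeric(9).
#' @export
mock_classifier <- function(alpha = Inf) {
  force(alpha)
  function(patch) {
    H <- dim(patch)[1]; W <- dim(patch)[2]
    flat <- matrix(patch, H * W, 3)
    key <- flat[, 1] * 1e6 + flat[, 2] * 1e3 + flat[, 3]
    ckey <- CLASS_COLORS[, 1] * 1e6 + CLASS_COLORS[, 2] * 1e3 + CLASS_COLORS[, 3]
    cls <- match(round(key, 6), round(ckey, 6))
    if (anyNA(cls)) stop("unknown color in patch: not one of the 9 class colors")
    frac <- tabulate(cls, nbins = 9L) / (H * W)
    if (!is.finite(alpha)) return(frac)
    pos <- frac > 0
    draw <- numeric(9)
    draw[pos] <- stats::rgamma(sum(pos), shape = alpha * frac[pos])
    if (sum(draw) == 0) return(frac)
    draw / sum(draw)
  }
}

#' Simulate a probability map directly (fast path)
#'
#' Bypasses image rendering: grid cells get true labels (border ring of
#' normal mucosa; interior tumor bed split STR/TUM to hit `target_tsr` up to
#' one-cell quantization), then probability vectors. Stroma cells put
#' Beta-distributed mass (mean `theta`, concentration `alpha`) on LYM and the
#' remainder on STR, so with `alpha = Inf` the Deep-TIL score of the map is
#' exactly `theta`; other cells concentrate on their true label with
#' Dirichlet(`alpha` * base) noise.
#'
#' @param target_tsr,theta Stroma fraction target and infiltration level,
#'   both in [0, 1]; `theta >= 0.5` would flip stroma cells to LYM at argmax
#'   and is rejected.
#' @param grid_dims Grid rows/cols, default `c(30, 30)`.
#' @param alpha Noise concentration; `Inf` = noise-free.
#' @param seed Optional integer seed.
#' @param meta Optional [slide_meta()]; a default HE meta is built otherwise.
#' @return List with `pmap` ([probability_map()]), `seg` (its argmax
#'   [segmentation_map()]) and `truth` (true label matrix).
#' @export
simulate_probability_map <- function(target_tsr, theta, grid_dims = c(30L, 30L),
                                     alpha = Inf, seed = NULL, meta = NULL) {
  if (target_tsr < 0 || target_tsr > 1) stop("target_tsr must lie in [0, 1]")
  if (theta < 0 || theta >= 0.5)
    stop("theta must lie in [0, 0.5): at 0.5 the stroma argmax flips to LYM")
  rows <- grid_dims[1]; cols <- grid_dims[2]
  if (rows < 3L || cols < 3L)
    stop("grid too small for target within quantization: need at least 3 x 3")
  if (is.null(meta)) meta <- slide_meta("synthetic", 224L, 112L, 0.5, "HE")
  with_seed(seed, {
    labels <- matrix(class_index("NOR"), rows, cols)
    edge <- row(labels) == 1 | row(labels) == rows |
      col(labels) == 1 | col(labels) == cols
    interior <- which(!edge)
    n_bed <- length(interior)
    n_str <- round(target_tsr * n_bed)
    labels[interior] <- class_index("TUM")
    if (n_str > 0L) labels[resample(interior, n_str)] <- class_index("STR")
    grid <- array(0, c(rows, cols, 9L))
    str_i <- class_index("STR"); lym_i <- class_index("LYM")
    for (cell in seq_len(rows * cols)) {
      lab <- labels[cell]
      v <- numeric(9)
      if (lab == str_i) {
        p_lym <- if (!is.finite(alpha)) theta else {
          if (theta == 0) 0 else stats::rbeta(1, theta * alpha, (1 - theta) * alpha)
        }
        v[lym_i] <- p_lym; v[str_i] <- 1 - p_lym
      } else if (!is.finite(alpha)) {
        v[lab] <- 1
      } else {
        base <- rep(0.05 / 8, 9); base[lab] <- 0.95
        g <- stats::rgamma(9, shape = alpha * base)
        v <- g / sum(g)
      }
      r <- ((cell - 1L) %% rows) + 1L; c <- ((cell - 1L) %/% rows) + 1L
      grid[r, c, ] <- v
    }
    pmap <- probability_map(grid, meta)
    list(pmap = pmap, seg = segment_map(pmap), truth = labels)
  })
}

#' Simulate one survival group from its 5-year rate
#'
#' Event times are exponential with rate `lambda = -log(s5) / 5`, so the true
#' survival at 5 years is exactly `s5`. Censoring combines an administrative
#' horizon with an optional uniform dropout: a `dropout_rate` fraction of
#' subjects get an independent uniform(0, horizon) censoring time.
#'
#' @param n Number of subjects.
#' @param s5 True 5-year survival in (0, 1) (alternative: give `lambda`).
#' @param lambda Exponential event rate; overrides `s5` when given.
#' @param censor_horizon Administrative censoring time, default 10 years;
#'   `Inf` disables it.
#' @param dropout_rate Fraction with uniform dropout, default 0.
#' @param seed Optional integer seed.
#' @return data.frame with `os_years`, `os_event` and the latent `true_time`.
#' @export
simulate_survival_group <- function(n, s5 = NULL, lambda = NULL,
                                    censor_horizon = 10, dropout_rate = 0,
                                    seed = NULL) {
  if (is.null(lambda)) {
    if (is.null(s5) || s5 <= 0 || s5 >= 1) stop("s5 must lie in (0, 1)")
    lambda <- -log(s5) / 5
  }
  if (lambda <= 0) stop("lambda must be > 0")
  with_seed(seed, {
    t_event <- stats::rexp(n, rate = lambda)
    cens <- rep(censor_horizon, n)
    if (dropout_rate > 0) {
      drop <- stats::runif(n) < dropout_rate
      cens[drop] <- pmin(cens[drop], stats::runif(sum(drop), 0, censor_horizon))
    }
    obs <- pmin(t_event, cens)
    data.frame(os_years = obs, os_event = as.integer(t_event <= cens),
               true_time = t_event)
  })
}

# uniform censoring max m such that P(C < T) = frac for a mix of exponential
# groups; C ~ U(0, m) independent of T
uniform_censor_max <- function(lambdas, frac) {
  # P(T > C) with C ~ U(0, m), T ~ Exp(lambda): (1 - exp(-lambda m)) / (lambda m)
  p_cens <- function(m) mean((1 - exp(-lambdas * m)) / (lambdas * m)) - frac
  stats::uniroot(p_cens, c(1e-6, 1e6))$root
}

#' Simulate a two-group proportional-hazards cohort
#'
#' Exponential event times with baseline rate `baseline_rate` in the
#' reference group and `baseline_rate * hr` in the comparison group, plus
#' independent uniform(0, m) censoring with m solved so that the expected
#' censored fraction equals `censor_fraction`.
#'
#' @param n_per_group Subjects per group.
#' @param hr True hazard ratio of group "g2" vs reference "g1".
#' @param baseline_rate Reference-group event rate per year, default 0.1.
#' @param censor_fraction Expected censored fraction, default 0.2.
#' @param seed Optional integer seed.
#' @return data.frame with `group` ("g1"/"g2"), `os_years`, `os_event`.
#' @export
simulate_two_group_cox <- function(n_per_group, hr, baseline_rate = 0.1,
                                   censor_fraction = 0.2, seed = NULL) {
  if (hr <= 0) stop("hr must be > 0")
  lambdas <- c(baseline_rate, baseline_rate * hr)
  with_seed(seed, {
    t_event <- c(stats::rexp(n_per_group, lambdas[1]),
                 stats::rexp(n_per_group, lambdas[2]))
    cens <- if (censor_fraction > 0) {
      stats::runif(2 * n_per_group, 0, uniform_censor_max(lambdas, censor_fraction))
    } else rep(Inf, 2 * n_per_group)
    data.frame(group = rep(c("g1", "g2"), each = n_per_group),
               os_years = pmin(t_event, cens),
               os_event = as.integer(t_event <= cens))
  })
}

# truncated-at-zero normal draw by rejection (sd small relative to mean here)
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x <= 0
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x <= 0
  }
  x
}

# place n points uniformly inside the stroma cells of a segmentation,
# returning slide pixel coordinates
place_in_stroma <- function(n, seg) {
  s <- seg$meta$stride_px
  cells <- which(seg$labels == class_index("STR"))
  if (!length(cells)) stop("no stroma ROI")
  pick <- if (n > 0) resample(cells, n, replace = TRUE) else integer(0)
  r <- ((pick - 1L) %% nrow(seg$labels))   # 0-based
  c <- ((pick - 1L) %/% nrow(seg$labels))
  cell_detections(x_px = c * s + stats::runif(n, 0, s),
                  y_px = r * s + stats::runif(n, 0, s),
                  slide_id = seg$meta$slide_id)
}

#' Simulate a full synthetic cohort
#'
#' Per patient: draws a stroma fraction and a latent infiltration level,
#' builds a probability map with [simulate_probability_map()], derives the
#' patient's true score groups from the generator's own rules (stroma cutoff
#' 0.5; infiltration tertiles of the cohort's latent levels), draws a CD3
#' density around the patient's immune-score group mean and places that many
#' detections homogeneously in the stroma (Poisson count), draws exponential
#' survival from the group hazard with administrative-plus-dropout censoring,
#' and draws clinical covariates. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param cohort_id Cohort label written into the clinical table.
#' @return List with `clinical` (clinical + survival table), `truth`
#'   (per-patient generator parameters and true groups), `maps` (named list
#'   of `pmap`/`seg` pairs, ready for [score_cohort()]) and `detections`
#'   (named list of `cell_detections`).
#' @export
simulate_cohort <- function(config = sim_config(), cohort_id = "synthetic") {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  with_seed(config$seed, {
    ids <- sprintf("P%04d", seq_len(n))
    tsr <- pmin(0.98, pmax(0.02, stats::rnorm(n, config$tsr_mean, config$tsr_sd)))
    theta <- stats::rbeta(n, config$theta_mean * config$theta_conc,
                          (1 - config$theta_mean) * config$theta_conc)
    theta <- pmin(theta, 0.49)
    # generator's own grouping: cutoff on true tsr, tertiles on true theta
    tg <- tsr_group(tsr, 0.5)
    cal <- calibrate_tertiles(theta, cohort_id)
    lg <- til_group(theta, cal)
    score <- immune_score(tg$points, lg$points)

    maps <- vector("list", n); names(maps) <- ids
    detections <- vector("list", n); names(detections) <- ids
    density_true <- numeric(n)
    for (i in seq_len(n)) {
      meta <- slide_meta(ids[i], 224L, 112L, 0.5,
                         stain = "HE")
      sim <- simulate_probability_map(tsr[i], theta[i], config$grid_dims,
                                      alpha = config$dirichlet_alpha, meta = meta)
      maps[[i]] <- sim[c("pmap", "seg")]
      mu <- config$density_means[score[i]]
      d <- if (config$density_sd_frac > 0)
        rnorm_pos(1, mu, config$density_sd_frac * mu) else mu
      density_true[i] <- d
      area <- stroma_area_mm2(sim$seg)
      n_cells <- stats::rpois(1, d * area)
      detections[[i]] <- place_in_stroma(n_cells, sim$seg)
    }

    lambda <- config$lambda[score]
    t_event <- stats::rexp(n, rate = lambda)
    cens <- rep(config$censor_horizon, n)
    if (config$dropout_rate > 0) {
      drop <- stats::runif(n) < config$dropout_rate
      cens[drop] <- pmin(cens[drop],
                         stats::runif(sum(drop), 0, config$censor_horizon))
    }
    os_years <- pmin(t_event, cens)
    os_event <- as.integer(t_event <= cens)

    stage_levels <- c("I", "II", "III")
    stage_p <- matrix(rep(config$stage_probs, n), n, 3, byrow = TRUE)
    if (config$stage_score_assoc > 0) {
      # shift probability mass toward stage III for low scores
      shift <- config$stage_score_assoc * (2.5 - score) / 1.5
      stage_p[, 3] <- pmin(0.95, pmax(0.05, stage_p[, 3] + 0.2 * shift))
      stage_p <- stage_p / rowSums(stage_p)
    }
    stage <- vapply(seq_len(n), function(i)
      sample(stage_levels, 1, prob = stage_p[i, ]), character(1))

    clinical <- data.frame(
      patient_id = ids, cohort = cohort_id,
      age = round(stats::rnorm(n, config$age_mean, config$age_sd), 1),
      sex = ifelse(stats::runif(n) < config$sex_prob_male, "male", "female"),
      stage = stage,
      location = ifelse(stats::runif(n) < config$location_prob_rectum,
                        "rectum", "colon"),
      grade = ifelse(stats::runif(n) < config$grade_prob_high, "high", "low"),
      cea = ifelse(stats::runif(n) < config$cea_prob_abnormal,
                   "abnormal", "normal"),
      os_years = os_years, os_event = os_event)

    truth <- data.frame(
      patient_id = ids, tsr_true = tsr, theta_true = theta,
      tsr_group_true = tg$group, til_group_true = lg$group,
      immune_score_true = score, density_true = density_true,
      lambda_true = lambda, event_time_true = t_event)

    list(clinical = clinical, truth = truth, maps = maps,
         detections = detections)
  })
}
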