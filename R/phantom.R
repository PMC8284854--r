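# Synthetic phantoms and source models: coefficient maps alpha_k(x) on a
# 1-D (128-bin) or 2-D (128 x 128) grid, component time courses mu_k(t)
# from region kinetics convolved with the injection AIFs, and complete
# replicable study designs.

#' Build a 1-D coefficient-profile phantom
#'
#' Each region contributes a non-negative coefficient profile alpha_k(x)
#' over the 1-D axis: a smooth Gaussian bump (default) or a hard plateau.
#' Smooth profiles are the default because source smoothness controls the
#' dose--MSE convergence rate of reconstruction.
#'
#' @param region_spec list of regions, each a list with `name`, `center`
#'   (bin, in 1..N), `width` (bins), `amplitude`, and optional `shape`
#'   (`"bump"` or `"plateau"`, default bump).  Plateau regions are
#'   treated as mutually exclusive and may not overlap.
#' @param N axis length (default 128).
#' @return An object of class `region_map`: list with `alpha` (K x N
#'   non-negative matrix), `names`, `N`.
#' @export
build_phantom_1d <- function(region_spec, N = 128) {
  if (length(region_spec) == 0) stop("empty region specification")
  x <- seq_len(N)
  K <- length(region_spec)
  alpha <- matrix(0, K, N)
  intervals <- list()
  for (k in seq_len(K)) {
    r <- region_spec[[k]]
    if (r$center < 1 || r$center > N) stop("region centre outside [1, N]")
    shape <- if (is.null(r$shape)) "bump" else r$shape
    if (shape == "plateau") {
      lo <- r$center - r$width / 2
      hi <- r$center + r$width / 2
      for (iv in intervals)
        if (lo < iv[2] && hi > iv[1])
          stop("overlapping exclusive (plateau) regions")
      intervals[[length(intervals) + 1L]] <- c(lo, hi)
      alpha[k, x >= lo & x <= hi] <- r$amplitude
    } else {
      alpha[k, ] <- r$amplitude * exp(-((x - r$center) / (r$width / 2))^2)
    }
  }
  if (all(alpha == 0)) stop("phantom has no non-zero region")
  out <- list(alpha = alpha, N = N,
              names = vapply(region_spec, function(r) r$name, ""))
  class(out) <- "region_map"
  out
}

#' Default six-region 1-D phantom
#'
#' Six smooth-bump tissue analogues (spleen, tumour, myocardium, normal
#' breast, liver, left ventricle) spread over the 128-bin axis, emulating
#' a body cross-section profile.
#'
#' @param N axis length.
#' @export
default_phantom_1d <- function(N = 128) {
  build_phantom_1d(list(
    list(name = "spleen",        center = 15,  width = 32, amplitude = 0.8),
    list(name = "tumour",        center = 38,  width = 28, amplitude = 1.0),
    list(name = "myocardium",    center = 60,  width = 24, amplitude = 0.9),
    list(name = "normal_breast", center = 80,  width = 40, amplitude = 0.6),
    list(name = "liver",         center = 102, width = 36, amplitude = 0.9),
    list(name = "lv",            center = 120, width = 20, amplitude = 1.0)
  ), N = N)
}

#' Disjoint-ROI plateau phantom
#'
#' Six mutually exclusive plateau regions covering the axis: the
#' region-of-interest layout used for kinetic-map recovery studies, where
#' every voxel belongs to exactly one tissue class (the setting in which
#' segment time courses are exactly proportional to their member voxels).
#'
#' @param N axis length.
#' @export
roi_phantom_1d <- function(N = 128) {
  build_phantom_1d(list(
    list(name = "spleen",        center = 11, width = 20, amplitude = 0.8,
         shape = "plateau"),
    list(name = "tumour",        center = 32, width = 20, amplitude = 1.0,
         shape = "plateau"),
    list(name = "myocardium",    center = 53, width = 20, amplitude = 0.9,
         shape = "plateau"),
    list(name = "normal_breast", center = 75, width = 22, amplitude = 0.6,
         shape = "plateau"),
    list(name = "liver",         center = 97, width = 20, amplitude = 0.9,
         shape = "plateau"),
    list(name = "lv",            center = 118, width = 20, amplitude = 1.0,
         shape = "plateau")
  ), N = N)
}

#' Build a 2-D coefficient-map phantom
#'
#' Regions are Gaussian blobs or hard discs on an `n x n` grid over the
#' unit square, giving K non-negative coefficient maps.
#'
#' @param region_spec list of regions, each a list with `name`, `center`
#'   (pixel coordinates, length 2), `width` (pixels), `amplitude`, and
#'   optional `shape` (`"blob"` default, or `"disc"`).
#' @param n grid size (default 128).
#' @return A `region_map` with `alpha` (K x n^2, voxels in column-major
#'   order) and `dim = c(n, n)`.
#' @export
build_phantom_2d <- function(region_spec, n = 128) {
  if (length(region_spec) == 0) stop("empty region specification")
  ix <- matrix(seq_len(n), n, n)
  iy <- matrix(seq_len(n), n, n, byrow = TRUE)
  K <- length(region_spec)
  alpha <- matrix(0, K, n * n)
  for (k in seq_len(K)) {
    r <- region_spec[[k]]
    d2 <- (ix - r$center[1])^2 + (iy - r$center[2])^2
    shape <- if (is.null(r$shape)) "blob" else r$shape
    m <- if (shape == "disc") r$amplitude * (d2 <= (r$width / 2)^2)
         else r$amplitude * exp(-d2 / (r$width / 2)^2)
    alpha[k, ] <- as.numeric(m)
  }
  if (all(alpha == 0)) stop("phantom has no non-zero region")
  out <- list(alpha = alpha, N = n * n, dim = c(n, n),
              names = vapply(region_spec, function(r) r$name, ""))
  class(out) <- "region_map"
  out
}

#' Default 2-D dual-tracer phantom (central-slice layout)
#'
#' Six smooth blobs on the 128 x 128 grid emulating a body cross-section
#' through the tumour region: breast tissue, tumour, myocardium/LV,
#' liver and spleen analogues.  Region names match the tissue classes of
#' [default_phantom_1d()] so the same kinetics apply.
#'
#' @param n grid size.
#' @export
default_phantom_2d <- function(n = 128) {
  build_phantom_2d(list(
    list(name = "spleen",        center = c(34, 94),  width = 26,
         amplitude = 0.8),
    list(name = "tumour",        center = c(44, 44),  width = 24,
         amplitude = 1.0),
    list(name = "myocardium",    center = c(78, 84),  width = 30,
         amplitude = 0.9),
    list(name = "normal_breast", center = c(56, 58),  width = 70,
         amplitude = 0.6),
    list(name = "liver",         center = c(92, 40),  width = 40,
         amplitude = 0.9),
    list(name = "lv",            center = c(80, 86),  width = 14,
         amplitude = 1.0)
  ), n = n)
}

#' Default four-region brain-like phantom for repeat-injection studies
#'
#' Grey-matter, white-matter, intermediate cortex and vascular analogues;
#' single-compartment kinetics in the grey/white flow range are the
#' natural companions (see [brain_kinetics_kety()]).
#'
#' @param N axis length.
#' @param shape `"bump"` (smooth, the default for resolution/dose work)
#'   or `"plateau"` (disjoint ROIs, used for kinetic-map recovery).
#' @export
brain_phantom_1d <- function(N = 128, shape = c("bump", "plateau")) {
  shape <- match.arg(shape)
  if (shape == "bump")
    return(build_phantom_1d(list(
      list(name = "grey",     center = 30,  width = 30, amplitude = 1.0),
      list(name = "white",    center = 70,  width = 28, amplitude = 0.8),
      list(name = "cortex2",  center = 100, width = 20, amplitude = 0.9),
      list(name = "vascular", center = 118, width = 8,  amplitude = 0.5)
    ), N = N))
  build_phantom_1d(list(
    list(name = "grey",     center = 16, width = 30, amplitude = 1.0,
         shape = "plateau"),
    list(name = "white",    center = 48, width = 30, amplitude = 0.8,
         shape = "plateau"),
    list(name = "cortex2",  center = 80, width = 30, amplitude = 0.9,
         shape = "plateau"),
    list(name = "vascular", center = 112, width = 30, amplitude = 0.5,
         shape = "plateau")
  ), N = N)
}

#' Kety parameters for the brain-like phantom regions
#'
#' Flow K_1 in the grey/white-matter range (0.2-0.9 mL/mL/min) with
#' partition coefficients K_1/k_2 between 0.6 and 1.0 mL/mL.
#'
#' @export
brain_kinetics_kety <- function() {
  list(grey     = c(K_1 = 0.80, partition = 0.95),
       white    = c(K_1 = 0.25, partition = 0.80),
       cortex2  = c(K_1 = 0.55, partition = 0.90),
       vascular = c(K_1 = 0.90, partition = 0.60))
}

#' Assemble a source model from a phantom, kinetics and injections
#'
#' Each region k and injection j has a kinetic specification: a Kety
#' one-compartment residue (`list(kind = "kety", K_1, k_2)`), an explicit
#' residue (`list(kind = "residue", R = residue_fn, delay = )`), or
#' nothing (`NULL`, no response to that injection).  The component curve
#' mu_k is the sum over injections of the residue convolved with that
#' injection's AIF, frame-averaged on the schedule; the source is
#' lambda(x, t) = sum_k alpha_k(x) mu_k(t).
#'
#' @param map a `region_map`.
#' @param kinetics list over regions, each a list over injections of
#'   kinetic specifications (see details).
#' @param injections list of `injection` objects.
#' @param schedule the full acquisition `frame_schedule`.
#' @param dt fine quadrature step, minutes.
#' @return An object of class `source_model`: list with `alpha` (K x N_x),
#'   `mu_frames` (K x N_T), `residues` (list region x injection),
#'   `delays`, `lambda_frames` (N_x x N_T), `injections`, `schedule`.
#' @export
build_source <- function(map, kinetics, injections, schedule,
                         dt = 1 / 600) {
  K <- nrow(map$alpha)
  if (length(kinetics) != K)
    stop("need one kinetic specification per region")
  J <- length(injections)
  T_E <- schedule_end(schedule)
  NT <- n_frames(schedule)
  mu_frames <- matrix(0, K, NT)
  residues <- vector("list", K)
  delays <- matrix(0, K, J)
  for (k in seq_len(K)) {
    spec_k <- kinetics[[k]]
    if (length(spec_k) != J)
      stop("kinetic specification/injection mismatch")
    residues[[k]] <- vector("list", J)
    for (j in seq_len(J)) {
      sp <- spec_k[[j]]
      if (is.null(sp)) next
      T_res <- T_E - injections[[j]]$window[1]
      R <- switch(sp$kind,
        kety = kety_residue(sp$K_1, sp$k_2, T_res),
        residue = sp$R,
        stop("unknown kinetic kind"))
      d <- if (is.null(sp$delay)) 0 else sp$delay
      residues[[k]][[j]] <- R
      delays[k, j] <- d
      mu_frames[k, ] <- mu_frames[k, ] +
        convolve_residue_aif(R, injections[[j]]$aif, d, schedule,
                             dt = dt)$value
    }
  }
  lambda_frames <- t(map$alpha) %*% mu_frames
  if (any(lambda_frames < -1e-10)) stop("negative source values")
  out <- list(alpha = map$alpha, mu_frames = mu_frames,
              residues = residues, delays = delays,
              lambda_frames = pmax(lambda_frames, 0),
              injections = injections, schedule = schedule,
              region_names = map$names)
  class(out) <- "source_model"
  out
}

#' Known-truth sub-TAC basis of a source model
#'
#' Builds the `subtac_basis` whose columns are the true component curves
#' mu_k with their true residues and delays -- the known-sub-TAC
#' conditioning used when studying coefficient-estimation error in
#' isolation.
#'
#' @param source a `source_model`.
#' @export
basis_from_source <- function(source) {
  subtacs <- lapply(seq_len(nrow(source$mu_frames)), function(k)
    subtac_known(source$residues[[k]], source$delays[k, ],
                 source$mu_frames[k, ]))
  basis_from_subtacs(subtacs, source$injections, source$schedule)
}

#' True kinetic parameter maps of a source model
#'
#' Voxel-level truth: the voxel residue for injection j is
#' sum_k alpha_k(x) R_kj, decomposed and summarised exactly as mapped
#' estimates are.
#'
#' @param source a `source_model`.
#' @param T_B large-vessel transit bound, minutes.
#' @return As [nprm_map()]: list per injection of voxels x 7 matrices.
#' @export
true_kinetic_maps <- function(source, T_B = 0.25) {
  basis <- basis_from_source(source)
  nv <- ncol(source$alpha)
  nprm_map_from_alpha(t(source$alpha), basis, T_B)
}

# shared path for truth maps / fitted maps given coefficient rows
nprm_map_from_alpha <- function(A, basis, T_B = 0.25) {
  nv <- nrow(A)
  J <- length(basis$injections)
  pars <- c("V_B", "V_D", "K_D", "K_i", "K_1", "extraction", "MTT")
  maps <- replicate(J, matrix(NA_real_, nv, length(pars),
                              dimnames = list(NULL, pars)),
                    simplify = FALSE)
  for (i in seq_len(nv)) {
    ks <- map_voxel_kinetics(A[i, ], basis, T_B)
    for (j in seq_len(J))
      maps[[j]][i, ] <- c(ks[[j]]$V_B, ks[[j]]$V_D, ks[[j]]$K_D,
                          ks[[j]]$K_i, ks[[j]]$K_1, ks[[j]]$extraction,
                          ks[[j]]$MTT)
  }
  attr(maps, "alpha") <- A
  maps
}

#' Specify a replicable simulation study design
#'
#' @param kind `"h2o_fdg"` (dual-tracer bolus water then infused FDG),
#'   `"repeat_h2o"` (J identical water injections), or `"fdg"` (a single
#'   FDG infusion study, the setting of the kinetic-map robustness and
#'   local-error analyses).
#' @param dose dose level; the supported grid is
#'   {0.3, 0.5, 0.7, 1, 1.5, 2.2, 3.2} unless `strict = FALSE`.
#' @param ratio_or_J water:FDG dose ratio (`h2o_fdg`; supported grid
#'   16, 20, 25, 32, 40, 51, 64) or the number of injections J
#'   (`repeat_h2o`; supported 2, 4, 6, 8).
#' @param N_R number of replicates (>= 1).
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param tau_ref expected total study counts at dose 1.
#' @param strict enforce the supported dose/ratio/J grids.
#' @return An object of class `study_design` with fields `kind`, `dose`,
#'   `ratio` or `J`, `tau` (total expected counts), `tau_split` (expected
#'   counts per injection), `N_R`, `seeds`, `schedule`, `injections`.
#' @export
make_study <- function(kind = c("h2o_fdg", "repeat_h2o", "fdg"), dose = 1,
                       ratio_or_J = if (kind == "h2o_fdg") 25 else 2,
                       N_R = 10, seed = 1, tau_ref = 1e9,
                       strict = TRUE) {
  kind <- match.arg(kind)
  if (N_R < 1) stop("N_R must be at least 1")
  dose_grid <- c(0.3, 0.5, 0.7, 1, 1.5, 2.2, 3.2)
  if (strict && !dose %in% dose_grid)
    stop("dose must be on the supported grid (or use strict = FALSE)")
  tau <- dose * tau_ref
  if (kind == "fdg") {
    schedule <- fdg_schedule()
    injections <- list(
      injection(synth_aif("fdg_infusion", onset = 1,
                          t_end = schedule_end(schedule)),
                window = c(0, schedule_end(schedule)), label = "fdg"))
    tau_split <- tau
    ratio <- NULL; J <- NULL
  } else if (kind == "h2o_fdg") {
    if (strict && !ratio_or_J %in% c(16, 20, 25, 32, 40, 51, 64))
      stop("dose ratio must be on the supported grid")
    sch_h2o <- h2o_schedule()
    sch_fdg <- fdg_schedule()
    schedule <- concat_schedules(sch_h2o, sch_fdg)
    t_split <- schedule_end(sch_h2o)
    injections <- list(
      injection(synth_aif("h2o_bolus", onset = 1, t_end = t_split),
                window = c(0, t_split), label = "h2o"),
      injection(synth_aif("fdg_infusion", onset = t_split + 1,
                          t_end = schedule_end(schedule)),
                window = c(t_split, schedule_end(schedule)),
                label = "fdg"))
    r <- ratio_or_J
    tau_split <- tau * c(r, 1) / (r + 1)
    ratio <- ratio_or_J; J <- NULL
  } else {
    J <- ratio_or_J
    if (strict && !J %in% c(2, 4, 6, 8))
      stop("number of injections must be 2, 4, 6 or 8")
    sch1 <- h2o_schedule()
    D1 <- schedule_end(sch1)
    schedule <- concat_schedules(replicate(J, sch1, simplify = FALSE))
    injections <- lapply(seq_len(J), function(j)
      injection(synth_aif("h2o_bolus", onset = (j - 1) * D1 + 1,
                          t_end = schedule_end(schedule)),
                window = c((j - 1) * D1, j * D1),
                label = sprintf("h2o_%d", j)))
    tau_split <- rep(tau / J, J)
    ratio <- NULL
  }
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, N_R)
  cal_seeds <- sample.int(2^31 - 2, 20)   # bandwidth-calibration replicates
  out <- list(kind = kind, dose = dose, ratio = ratio, J = J,
              tau = tau, tau_split = tau_split, N_R = N_R, seed = seed,
              seeds = seeds, cal_seeds = cal_seeds,
              schedule = schedule, injections = injections)
  class(out) <- "study_design"
  out
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "Study design (%s): dose %.2g, %s, %d replicates, %d frames\n",
    x$kind, x$dose,
    if (x$kind == "h2o_fdg") sprintf("ratio %g:1", x$ratio)
    else sprintf("J = %d", x$J),
    x$N_R, n_frames(x$schedule)))
  invisible(x)
}

#' Default source model for a study design
#'
#' `h2o_fdg`: the six-tissue phantom with one-compartment water kinetics
#' and two-compartment-like FDG kinetics (explicit residues with a
#' trapping component for tumour/myocardium/liver).  `repeat_h2o`: the
#' brain-like phantom with grey/white-range Kety kinetics repeated at
#' every injection.
#'
#' @param design a `study_design`.
#' @param dt fine quadrature step.
#' @param map optional `region_map` overriding the default phantom; its
#'   region names must match the default tissue classes of the design
#'   kind (e.g. [roi_phantom_1d()] for `h2o_fdg`).
#' @export
default_source <- function(design, dt = 1 / 600, map = NULL) {
  T_E <- schedule_end(design$schedule)
  if (design$kind == "repeat_h2o") {
    if (is.null(map)) map <- brain_phantom_1d()
    kp <- brain_kinetics_kety()
    kinetics <- lapply(map$names, function(nm) {
      p <- kp[[nm]]
      lapply(seq_along(design$injections), function(j)
        list(kind = "kety", K_1 = p[["K_1"]],
             k_2 = p[["K_1"]] / p[["partition"]]))
    })
    return(build_source(map, kinetics, design$injections,
                        design$schedule, dt = dt))
  }
  if (is.null(map)) map <- default_phantom_1d()
  # water: one-compartment flow kinetics; FDG: residues with slow washout
  # plus a trapped (constant) component representing metabolic flux
  fdg_res <- function(K_1, k_2, K_i, T_res) {
    wash <- kety_residue(K_1 - K_i, k_2, T_res)
    residue_combine(list(wash, residue_fn(c(0, T_res), c(K_i, K_i))),
                    c(1, 1))
  }
  h2o <- list(spleen = c(0.60, 0.70), tumour = c(0.45, 0.55),
              myocardium = c(0.85, 0.90), normal_breast = c(0.20, 0.35),
              liver = c(0.70, 0.75), lv = c(0.95, 3.0))
  fdg <- list(spleen = c(0.35, 0.50, 0.010), tumour = c(0.30, 0.45, 0.035),
              myocardium = c(0.60, 0.70, 0.040),
              normal_breast = c(0.12, 0.40, 0.004),
              liver = c(0.55, 0.60, 0.008), lv = c(0.80, 2.5, 0.002))
  # water kinetics: K_1 = w[1] (mL/mL/min), k_2 = w[2] (washout rate, 1/min)
  if (design$kind == "fdg") {
    kinetics <- lapply(map$names, function(nm) {
      f <- fdg[[nm]]
      list(list(kind = "residue", R = fdg_res(f[1], f[2], f[3], T_E)))
    })
  } else {
    kinetics <- lapply(map$names, function(nm) {
      w <- h2o[[nm]]; f <- fdg[[nm]]
      T_res2 <- T_E - design$injections[[2]]$window[1]
      list(list(kind = "kety", K_1 = w[1], k_2 = w[2]),
           list(kind = "residue", R = fdg_res(f[1], f[2], f[3], T_res2)))
    })
  }
  build_source(map, kinetics, design$injections, design$schedule, dt = dt)
}

#' Relative voxel noise at the peak frame (calibration hook)
#'
#' Simulates one replicate at the design dose and reports the ratio of
#' the reconstruction error SD to the true peak source value, the
#' quantity used to calibrate `tau_ref` so that simulated noise matches a
#' target band.
#'
#' @param design a `study_design`.
#' @param source a `source_model` (default from [default_source()]).
#' @param cfg a `scanner_1d_config` (tau is overridden by the design).
#' @export
calibrate_noise <- function(design, source = default_source(design),
                            cfg = scanner_1d_config()) {
  cfg$tau <- design$tau
  set.seed(design$seeds[1])
  sim <- simulate_study_1d(source$lambda_frames, design$schedule$duration_s / 60,
                           cfg, recon = "fbp")
  peak_frame <- which.max(apply(source$lambda_frames, 2, max))
  err <- sim$recon[, peak_frame] - source$lambda_frames[, peak_frame]
  stats::sd(err) / max(source$lambda_frames[, peak_frame])
}
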