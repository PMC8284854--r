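# Step 2 of NPRM: assemble candidate basis columns (modelled sub-TACs plus
# per-injection AIF-spike and Patlak supplements) and prune them by
# cross-validation guided backwards elimination against the reduced
# dataset.

#' Build the sub-TAC basis by cross-validation guided elimination
#'
#' Candidate columns are the modelled segment sub-TACs supplemented, for
#' each injection, with the frame-averaged AIF (the exact model of a spike
#' residue) and the frame-averaged running integral of the AIF (the Patlak
#' element, corresponding to a constant residue).  Backwards elimination
#' removes, at each step, the column whose removal least degrades the
#' cross-validated weighted fit of the reduced dataset under non-negative
#' fitting, and stops when any removal would degrade the CV error by more
#' than `tol` (relative).  Folds are interleaved subsets of time frames:
#' coefficients fitted on the training frames of each segment predict its
#' held-out frames.
#'
#' @param modelled list of `subtac` objects (from
#'   [select_segment_model()] or [fit_subtac()]).
#' @param DS a `reduced_dataset` used to score candidate bases.
#' @param injections list of `injection` objects.
#' @param schedule the acquisition `frame_schedule`.
#' @param cv_folds number of folds over time frames (default 5).
#' @param tol relative CV-error increase tolerated when removing a column.
#' @param weighted use weighted (1/sigma^2) CV error (default) or
#'   unweighted.
#' @param dt fine quadrature step for the supplement columns.
#' @return An object of class `subtac_basis`: list with `X` (N_T x K
#'   matrix of sub-TAC curves), `columns` (per-column metadata: kind,
#'   delays, residues), `K_r` (indices of residue-kind columns, Patlak
#'   included as a constant residue), `injections`, `schedule`.
#' @export
build_basis <- function(modelled, DS, injections, schedule,
                        cv_folds = 5, tol = 0.02, weighted = TRUE,
                        dt = 1 / 600) {
  if (length(modelled) == 0) stop("empty candidate set")
  T_E <- schedule_end(schedule)
  tgrid <- conv_grid(T_E, dt)
  cols <- lapply(modelled, function(s) {
    list(kind = s$kind, delays = s$delays, residues = s$residues,
         curve = s$curve)
  })
  for (j in seq_along(injections)) {
    inj <- injections[[j]]
    cp <- curve_at(inj$aif, tgrid)
    spike <- frame_average(tgrid, cp, schedule)
    patlak <- frame_average(tgrid, cum_integral(tgrid, cp), schedule)
    cols[[length(cols) + 1L]] <-
      list(kind = "aif_spike", delays = rep(0, length(injections)),
           residues = NULL, curve = spike, supplement_inj = j)
    T_res <- T_E - inj$window[1]
    const_res <- lapply(seq_along(injections), function(jj)
      if (jj == j) residue_fn(c(0, T_res), c(1, 1)) else NULL)
    cols[[length(cols) + 1L]] <-
      list(kind = "patlak", delays = rep(0, length(injections)),
           residues = const_res, curve = patlak, supplement_inj = j)
  }

  X <- vapply(cols, function(c) c$curve, numeric(n_frames(schedule)))
  X <- matrix(X, nrow = n_frames(schedule))
  keep <- which(colSums(abs(X)) > 0)       # degenerate columns go first
  if (length(keep) == 0) stop("all candidate columns are zero")

  NT <- n_frames(schedule)
  folds <- split(seq_len(NT), rep_len(seq_len(cv_folds), NT))
  W <- if (weighted) 1 / DS$sds^2 else matrix(1, DS$S, NT)

  cv_error <- function(active) {
    Xa <- X[, active, drop = FALSE]
    err <- 0
    for (s in seq_len(DS$S)) {
      z <- DS$means[s, ]
      w <- W[s, ]
      for (f in folds) {
        tr <- setdiff(seq_len(NT), f)
        fit <- wnnls(sqrt(w[tr]) * Xa[tr, , drop = FALSE],
                     sqrt(w[tr]) * z[tr])
        pred <- drop(Xa[f, , drop = FALSE] %*% fit$x)
        err <- err + sum(w[f] * (z[f] - pred)^2)
      }
    }
    err
  }

  current <- cv_error(keep)
  while (length(keep) > 1) {
    trial <- vapply(seq_along(keep),
                    function(i) cv_error(keep[-i]), numeric(1))
    i_best <- which.min(trial)
    if (trial[i_best] <= current * (1 + tol)) {
      keep <- keep[-i_best]
      current <- trial[i_best]
    } else break
  }

  cols <- cols[keep]
  K_r <- which(vapply(cols, function(c)
    c$kind %in% c("residue", "patlak") && !is.null(c$residues), logical(1)))
  out <- list(X = X[, keep, drop = FALSE], columns = cols, K_r = K_r,
              injections = injections, schedule = schedule,
              cv_error = current)
  class(out) <- "subtac_basis"
  out
}

#' Assemble a basis directly from sub-TACs without elimination
#'
#' Convenience for simulation studies with a known source model: each
#' sub-TAC becomes one column; all residue-kind columns enter `K_r`.
#'
#' @param subtacs list of `subtac` objects.
#' @param injections list of `injection` objects.
#' @param schedule the acquisition `frame_schedule`.
#' @export
basis_from_subtacs <- function(subtacs, injections, schedule) {
  cols <- lapply(subtacs, function(s)
    list(kind = s$kind, delays = s$delays, residues = s$residues,
         curve = s$curve))
  X <- matrix(vapply(cols, function(c) c$curve,
                     numeric(n_frames(schedule))),
              nrow = n_frames(schedule))
  K_r <- which(vapply(cols, function(c)
    !is.null(c$residues), logical(1)))
  out <- list(X = X, columns = cols, K_r = K_r,
              injections = injections, schedule = schedule,
              cv_error = NA_real_)
  class(out) <- "subtac_basis"
  out
}

#' @export
print.subtac_basis <- function(x, ...) {
  cat(sprintf("Sub-TAC basis: %d columns (%d residue-kind) x %d frames\n",
              ncol(x$X), length(x$K_r), nrow(x$X)))
  invisible(x)
}

#' Non-negative voxel fit against a sub-TAC basis
#'
#' Solves the voxel-level linear model z ~ X alpha with alpha >= 0 by
#' non-negative (optionally weighted) least squares.
#'
#' @param z voxel time course, length N_T.
#' @param basis a `subtac_basis`, or a plain N_T x K matrix.
#' @param weights optional positive frame weights.
#' @return An object of class `voxel_fit`: `alpha` (non-negative
#'   coefficients), `fitted` (X alpha), `resid_rms` (root mean square
#'   data residual), `sse` (weighted residual sum of squares).
#' @export
fit_voxel <- function(z, basis, weights = NULL) {
  X <- if (inherits(basis, "subtac_basis")) basis$X else as.matrix(basis)
  z <- as.numeric(z)
  if (length(z) != nrow(X)) stop("voxel curve length does not match basis")
  if (any(!is.finite(z)) || any(!is.finite(X))) stop("non-finite input")
  sw <- if (is.null(weights)) rep(1, nrow(X)) else sqrt(weights)
  fit <- wnnls(sw * X, sw * z)
  fitted <- drop(X %*% fit$x)
  out <- list(alpha = fit$x, fitted = fitted,
              resid_rms = sqrt(mean((z - fitted)^2)),
              sse = fit$sse)
  class(out) <- "voxel_fit"
  out
}

#' Map voxel kinetics from a fitted coefficient vector
#'
#' The voxel residue for each injection is the non-negative combination of
#' the residue-kind basis columns' residues; kinetic summaries follow from
#' its decomposition.  The voxel delay is the flow-weighted average of the
#' column delays: sum(alpha_k K_Dk delta_k) / sum(alpha_k K_Dk) over
#' residue columns.
#'
#' @param fit a `voxel_fit` (or bare non-negative coefficient vector).
#' @param basis the `subtac_basis` used for the fit.
#' @param T_B large-vessel transit bound, minutes.
#' @return A list with one `kinetic_summaries` per injection; attribute
#'   `has_residue` is FALSE (and all summaries zero) when the basis has no
#'   residue-kind columns.
#' @export
map_voxel_kinetics <- function(fit, basis, T_B = 0.25) {
  alpha <- if (inherits(fit, "voxel_fit")) fit$alpha else as.numeric(fit)
  J <- length(basis$injections)
  zero_sum <- function() {
    out <- list(V_B = 0, V_D = 0, K_D = 0, K_i = 0, K_1 = 0,
                extraction = NA_real_, MTT = NA_real_, delay = 0,
                MTT_defined = FALSE, extraction_defined = FALSE)
    class(out) <- "kinetic_summaries"
    out
  }
  if (length(basis$K_r) == 0) {
    out <- replicate(J, zero_sum(), simplify = FALSE)
    attr(out, "has_residue") <- FALSE
    return(out)
  }
  out <- vector("list", J)
  for (j in seq_len(J)) {
    ks <- basis$K_r[vapply(basis$K_r, function(k)
      !is.null(basis$columns[[k]]$residues[[j]]), logical(1))]
    if (length(ks) == 0 || sum(alpha[ks]) == 0) {
      out[[j]] <- zero_sum()
      next
    }
    Rs <- lapply(ks, function(k) basis$columns[[k]]$residues[[j]])
    Rsum <- residue_combine(Rs, alpha[ks])
    dec <- residue_decompose(Rsum, T_B = T_B)
    # flow-weighted delay over the contributing residue columns
    KDk <- vapply(seq_along(ks), function(i) {
      d <- residue_decompose(Rs[[i]], T_B = T_B)
      d$R_D$knot_values[1]
    }, numeric(1))
    dk <- vapply(ks, function(k) basis$columns[[k]]$delays[j], numeric(1))
    wsum <- sum(alpha[ks] * KDk)
    delay_bar <- if (wsum > 0) sum(alpha[ks] * KDk * dk) / wsum else 0
    out[[j]] <- residue_summaries(dec, delay = delay_bar)
  }
  attr(out, "has_residue") <- TRUE
  out
}

#' Voxel-wise kinetic parameter maps
#'
#' Runs [fit_voxel()] and [map_voxel_kinetics()] over every voxel of a
#' dynamic image and collects parameter maps.
#'
#' @param Z dynamic image, voxels x N_T.
#' @param basis a `subtac_basis`.
#' @param weights optional frame weights shared by all voxels.
#' @param T_B large-vessel transit bound, minutes.
#' @return A list with one element per injection, each a voxels x 7 matrix
#'   with columns V_B, V_D, K_D, K_i, K_1, extraction, MTT (NA where
#'   undefined), plus attribute `alpha` (voxels x K coefficient matrix).
#' @export
nprm_map <- function(Z, basis, weights = NULL, T_B = 0.25) {
  Z <- as.matrix(Z)
  nv <- nrow(Z)
  J <- length(basis$injections)
  pars <- c("V_B", "V_D", "K_D", "K_i", "K_1", "extraction", "MTT")
  maps <- replicate(J, matrix(NA_real_, nv, length(pars),
                              dimnames = list(NULL, pars)),
                    simplify = FALSE)
  A <- matrix(0, nv, ncol(basis$X))
  for (i in seq_len(nv)) {
    f <- fit_voxel(Z[i, ], basis, weights)
    A[i, ] <- f$alpha
    ks <- map_voxel_kinetics(f, basis, T_B)
    for (j in seq_len(J))
      maps[[j]][i, ] <- c(ks[[j]]$V_B, ks[[j]]$V_D, ks[[j]]$K_D,
                          ks[[j]]$K_i, ks[[j]]$K_1, ks[[j]]$extraction,
                          ks[[j]]$MTT)
  }
  attr(maps, "alpha") <- A
  maps
}
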