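#' Mutual information between two volumes on a shared grid
#'
#' Computed in nats from a `bins x bins` joint histogram over the joint
#' foreground (voxels where both images are nonzero), with equal-width
#' bins spanning each image's own foreground min-max. MI is the similarity
#' maximised by the cross-modal registration pass (PET to structural MRI),
#' because it assumes no particular functional relation between the two
#' intensity distributions.
#'
#' @param a,b [pet_volume]s on the same grid.
#' @param bins number of histogram bins per image (>= 2).
#' @return Nonnegative scalar, nats.
#' @export
mutual_information <- function(a, b, bins = 64L) {
  stopifnot(inherits(a, "pet_volume"), inherits(b, "pet_volume"), bins >= 2)
  if (!same_grid(a, b)) stop("volumes must share a grid", call. = FALSE)
  av <- as.numeric(a$data); bv <- as.numeric(b$data)
  fga <- av != 0; fgb <- bv != 0
  if (!any(fga & fgb)) stop("no overlap: joint foreground is empty", call. = FALSE)
  st <- cpp_joint_stats(av, bv, as.integer(bins),
                        min(av[fga]), max(av[fga]),
                        min(bv[fgb]), max(bv[fgb]), 0L)
  mi_from_joint(st$joint)
}

mi_from_joint <- function(joint) {
  n <- sum(joint)
  p <- joint / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  ex <- outer(px, py)
  sum(p[nz] * log(p[nz] / ex[nz]))
}

#' Correlation ratio between two volumes on a shared grid
#'
#' `eta^2 = 1 - sum_k n_k Var(b | a-bin k) / (N Var(b))` over the joint
#' foreground, with `a` binned into `bins` equal-width bins. Ranges over
#' [0, 1]; 1 when `b` is a function of `a`. This is the similarity used by
#' the within-modality registration pass (PET to PET template) and by the
#' automated registration QC score.
#'
#' @inheritParams mutual_information
#' @param mask_mode `"joint"` (both nonzero; the default) or `"target"`
#'   (only `a` nonzero), the latter used by [qc_score()].
#' @return Scalar in [0, 1].
#' @export
correlation_ratio <- function(a, b, bins = 64L,
                              mask_mode = c("joint", "target")) {
  stopifnot(inherits(a, "pet_volume"), inherits(b, "pet_volume"), bins >= 2)
  mask_mode <- match.arg(mask_mode)
  if (!same_grid(a, b)) stop("volumes must share a grid", call. = FALSE)
  av <- as.numeric(a$data); bv <- as.numeric(b$data)
  fga <- av != 0
  if (mask_mode == "joint") {
    sel <- fga & bv != 0
  } else {
    sel <- fga
  }
  if (!any(sel)) stop("no overlap: joint foreground is empty", call. = FALSE)
  st <- cpp_joint_stats(av, bv, as.integer(bins),
                        min(av[fga]), max(av[fga]),
                        min(bv[sel]), max(bv[sel]),
                        if (mask_mode == "joint") 0L else 1L)
  N <- st$n
  var_b <- st$b_sum2 / N - (st$b_sum / N)^2
  if (var_b <= 0) stop("degenerate target intensity: Var(b) = 0", call. = FALSE)
  keep <- st$n_k > 0
  within <- st$sum2_k[keep] - st$sum_k[keep]^2 / st$n_k[keep]
  eta2 <- 1 - sum(within) / (N * var_b)
  min(max(eta2, 0), 1)
}

#' Automated registration quality-control score
#'
#' Correlation ratio of the registered image against the target, computed
#' over the target foreground mask. Replaces the visual pass/fail
#' assessment of registrations with a deterministic score in [0, 1]; a
#' registration passes QC when the score reaches the configured threshold.
#'
#' @param registered,target [pet_volume]s on the same grid.
#' @param bins histogram bins.
#' @return Scalar in [0, 1].
#' @export
qc_score <- function(registered, target, bins = 64L) {
  correlation_ratio(target, registered, bins = bins, mask_mode = "target")
}

#' Optimizer settings for affine registration
#'
#' @param bins histogram bins at full resolution (coarser pyramid levels
#'   use proportionally fewer).
#' @param pyramid integer downsampling factors, coarse to fine.
#' @param maxit Nelder-Mead iteration budget per pyramid level (same
#'   length as `pyramid`).
#' @param qc_threshold QC pass threshold in [0, 1].
#' @param coarse_restarts extra optimizer restarts at the coarsest level.
#' @param reltol simplex relative-tolerance stopping rule.
#' @return A list of settings for [register_affine()].
#' @export
registration_config <- function(bins = 64L, pyramid = c(4L, 2L, 1L),
                                maxit = c(800L, 400L, 1000L),
                                qc_threshold = 0.90,
                                coarse_restarts = 1L,
                                reltol = 1e-5) {
  stopifnot(length(maxit) == length(pyramid))
  list(bins = as.integer(bins), pyramid = as.integer(pyramid),
       maxit = as.integer(maxit), qc_threshold = qc_threshold,
       coarse_restarts = as.integer(coarse_restarts), reltol = reltol)
}

reg_param_vector <- function(tr) {
  c(tr$translation_mm, tr$rotation_rad, log(tr$scale), tr$shear)
}

reg_param_transform <- function(p, center) {
  affine_transform(translation_mm = p[1:3], rotation_rad = p[4:6],
                   scale = exp(p[7:9]), shear = p[10:12], center = center)
}

#' 12-dof affine intensity-based registration
#'
#' Finds the affine transform mapping `source` anatomy onto `target` that
#' maximises the chosen similarity, using a multi-resolution pyramid and a
#' derivative-free Nelder-Mead search at each level with parameters
#' propagated coarse-to-fine. Rotations and scales pivot about the centre
#' of mass of the target foreground. Deterministic given inputs, `init`
#' and `config`.
#'
#' @param source,target [pet_volume]s; `source` is moved onto `target`.
#' @param cost `"mutual_information"` (cross-modal) or
#'   `"correlation_ratio"` (within-modality).
#' @param init an [affine_transform] initial guess (identity default).
#' @param config see [registration_config()].
#' @return A list of class `registration_result`: `transform`
#'   (an [affine_transform]), `matrix`, `final_cost`, `cost_name`,
#'   `qc_score`, `qc_pass`, `iterations`, `converged`.
#' @export
register_affine <- function(source, target,
                            cost = c("mutual_information", "correlation_ratio"),
                            init = affine_identity(),
                            config = registration_config()) {
  cost <- match.arg(cost)
  stopifnot(inherits(source, "pet_volume"), inherits(target, "pet_volume"))
  src_fg <- source$data != 0
  if (!any(src_fg) || length(unique(source$data[src_fg])) < 2) {
    stop("source has empty or constant foreground", call. = FALSE)
  }
  tgt_fg <- target$data != 0
  if (!any(tgt_fg)) stop("target is empty", call. = FALSE)
  w <- voxel_world_coords(target, tgt_fg)
  center <- colSums(w * target$data[tgt_fg]) / sum(target$data[tgt_fg])

  similarity <- function(tvol, moved, bins) {
    val <- tryCatch({
      if (cost == "mutual_information") mutual_information(moved, tvol, bins)
      else correlation_ratio(tvol, moved, bins)
    }, error = function(e) NA_real_)
    if (!is.finite(val)) -1e6 else val
  }

  p <- reg_param_vector(init)
  parscale <- c(rep(4, 3), rep(0.04, 3), rep(0.04, 3), rep(0.02, 3))
  total_it <- 0L
  converged <- TRUE
  cost_type <- if (cost == "mutual_information") 0L else 1L
  for (lev in seq_along(config$pyramid)) {
    f <- config$pyramid[lev]
    s_lev <- downsample_volume(source, f)
    t_lev <- downsample_volume(target, f)
    bins_lev <- max(16L, as.integer(config$bins / f))
    svec <- as.numeric(s_lev$data)
    sdim <- dim(s_lev$data)
    tfg_idx <- which(t_lev$data != 0, arr.ind = TRUE)
    tval <- t_lev$data[t_lev$data != 0]
    tmin <- min(tval); tmax <- max(tval)
    fi <- as.integer(tfg_idx[, 1] - 1L)
    fj <- as.integer(tfg_idx[, 2] - 1L)
    fk <- as.integer(tfg_idx[, 3] - 1L)
    Ainv_src <- solve(s_lev$affine)
    A_tgt <- t_lev$affine
    obj <- function(pv) {
      Tm <- affine_matrix(reg_param_transform(pv, center))
      M <- Ainv_src %*% solve(Tm) %*% A_tgt
      -cpp_reg_cost_masked(svec, sdim, M, fi, fj, fk, tval, bins_lev,
                           tmin, tmax, cost_type)
    }
    # coarsest level: staged search (translation, then rigid, then full
    # 12-dof) to avoid local minima under large initial misalignments
    # block-relaxed search, two cycles: rigid block, then scale/shear
    # block, then all 12 parameters; low-dimensional blocks resolve the
    # shallow couplings between rotation and scale/shear on smooth head
    # shapes, and the second cycle escapes premature simplex collapse
    stages <- if (lev < length(config$pyramid)) {
      list(1:6, 7:12, 1:12, 1:6, 7:12, 1:12)
    } else {
      list(1:6, 7:12, 1:12)
    }
    nstart <- if (lev == 1L) 1L + config$coarse_restarts else 1L
    if (lev == 1L) {
      # rotation seeding: coarse grid over initial rotations; smooth
      # head shapes give shallow rotational basins that trap the simplex
      p_t <- p
      rgrid <- c(-8, -4, 0, 4, 8) * pi / 180
      grid <- expand.grid(rx = rgrid, ry = rgrid, rz = rgrid)
      fit_t <- stats::optim(p[1:3], function(ps) {
        pv <- p_t; pv[1:3] <- ps; obj(pv)
      }, method = "Nelder-Mead",
      control = list(maxit = config$maxit[1], parscale = parscale[1:3],
                     reltol = config$reltol))
      p[1:3] <- fit_t$par
      total_it <- total_it + fit_t$counts[["function"]]
      costs <- apply(grid, 1, function(g) {
        pv <- p; pv[4:6] <- as.numeric(g); obj(pv)
      })
      p[4:6] <- as.numeric(grid[which.min(costs), ])
      total_it <- total_it + nrow(grid)
      stages <- list(1:6, 1:12)
    }
    for (stage in stages) {
      obj_stage <- function(ps) {
        pv <- p
        pv[stage] <- ps
        obj(pv)
      }
      for (rep in seq_len(nstart)) {
        fit <- stats::optim(p[stage], obj_stage, method = "Nelder-Mead",
                            control = list(maxit = config$maxit[lev],
                                           parscale = parscale[stage],
                                           reltol = config$reltol))
        p[stage] <- fit$par
        total_it <- total_it + fit$counts[["function"]]
      }
    }
    if (lev == length(config$pyramid)) {
      converged <- fit$convergence == 0L
    }
  }
  transform <- reg_param_transform(p, center)
  moved_full <- resample(source, transform, target)
  final_cost <- similarity(target, moved_full, config$bins)
  qc <- tryCatch(qc_score(moved_full, target, bins = config$bins),
                 error = function(e) 0)
  if (!converged) {
    warning("registration did not converge at the finest level; ",
            "returning best-seen parameters", call. = FALSE)
  }
  structure(list(transform = transform, matrix = affine_matrix(transform),
                 final_cost = final_cost, cost_name = cost,
                 qc_score = qc,
                 qc_pass = converged && qc >= config$qc_threshold,
                 iterations = total_it, converged = converged),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result> cost =", x$cost_name,
      sprintf("(%.4f)", x$final_cost),
      "| qc =", sprintf("%.3f", x$qc_score),
      if (x$qc_pass) "[pass]" else "[fail]", "\n")
  print(x$transform)
  invisible(x)
}
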