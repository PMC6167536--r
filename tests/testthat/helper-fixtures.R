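# Shared fixtures, built once per test run and cached. The expensive ones
# (control database, template bundle) are only constructed when a test
# first asks for them.

.fx <- new.env(parent = emptyenv())

fx_spec <- function() {
  if (is.null(.fx$spec)) .fx$spec <- phantom_spec(seed = 20180101L)
  .fx$spec
}

fx_anatomy <- function() {
  if (is.null(.fx$anatomy)) .fx$anatomy <- make_anatomy(fx_spec())
  .fx$anatomy
}

# canonical-space PET template (PSF-matched blur of the reference)
fx_template <- function() {
  if (is.null(.fx$template)) {
    .fx$template <- gaussian_smooth(fx_anatomy()$pet_reference, 6)
  }
  .fx$template
}

fx_config <- function() run_config("spm_style")

# 30 control scans processed into template space (smoothing + spatial
# normalization), without intensity normalization: control databases for
# any normalization mode derive from these
fx_controls_in_template <- function(n = 30L) {
  key <- paste0("ctl_tpl_", n)
  if (is.null(.fx[[key]])) {
    an <- fx_anatomy()
    cfg <- fx_config()
    .fx[[key]] <- lapply(seq_len(n), function(s) {
      ctl <- simulate_control(fx_spec(), s, anatomy = an)
      pedpet:::process_scan(ctl$volume, fx_template(), cfg,
                            normalize = FALSE)$volume
    })
  }
  .fx[[key]]
}

fx_control_stats <- function(mode = "cerebellum_gm", n = 30L) {
  key <- paste0("stats_", mode, "_", n)
  if (is.null(.fx[[key]])) {
    ref_mask <- if (mode == "cerebellum_gm") {
      lobe_mask(fx_anatomy()$atlas, "cerebellum")
    } else NULL
    .fx[[key]] <- build_control_stats(fx_controls_in_template(n),
                                      normalization_mode = mode,
                                      reference_mask = ref_mask)
  }
  .fx[[key]]
}

# small deterministic t-map scaffold for cluster tests
fx_flat_statmap <- function(dim = c(20L, 20L, 20L), df = 29L) {
  t0 <- array(0, dim = dim)
  structure(list(t = pet_volume(t0, diag(c(3, 3, 3, 1))), df = df,
                 mask = array(TRUE, dim = dim),
                 flagged = array(FALSE, dim = dim)),
            class = "stat_map")
}

# brute-force flood fill, the oracle for connected-component labelling
flood_fill_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(offs))
  offs <- offs[ord > 0 & ord <= c("6" = 1, "18" = 2, "26" = 3)[as.character(connectivity)], ,
               drop = FALSE]
  nxt <- 0L
  for (lin in which(mask)) {
    if (labels[lin] != 0L) next
    nxt <- nxt + 1L
    queue <- lin
    labels[lin] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      idx <- arrayInd(cur, d)
      for (o in seq_len(nrow(offs))) {
        nb <- idx + offs[o, ]
        if (any(nb < 1) || any(nb > d)) next
        nl <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
        if (mask[nl] && labels[nl] == 0L) {
          labels[nl] <- nxt
          queue <- c(queue, nl)
        }
      }
    }
  }
  labels
}

# RMS world-space displacement of brain voxels under the composition of a
# recovered registration with the true subject transform (identity when
# recovery is perfect)
recovery_rms_mm <- function(recovered_matrix, true_transform, reference) {
  err <- recovered_matrix %*% affine_matrix(true_transform)
  mask <- reference$data != 0
  w <- pedpet:::voxel_world_coords(reference, mask)
  wp <- cbind(w, 1) %*% t(err)
  sqrt(mean(rowSums((wp[, 1:3] - w)^2)))
}
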