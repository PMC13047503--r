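#' CASL quantification parameters
#'
#' Constants of the single-compartment continuous-ASL perfusion model:
#' blood-brain partition coefficient `lambda` (ml/g), labeling efficiency
#' `alpha`, and the unit conversion from ml/g/s to ml 100g^-1 min^-1.
#' Defaults follow common rodent CASL practice and are configurable.
#'
#' @param lambda_partition Blood-brain partition coefficient, ml/g
#'   (default 0.90).
#' @param alpha_label Labeling efficiency in (0, 1] (default 0.70).
#' @param unit_scale ml/g/s to ml 100g^-1 min^-1 factor (default 6000).
#' @return Object of class `asl_params`.
#' @export
asl_params <- function(lambda_partition = 0.90, alpha_label = 0.70,
                       unit_scale = 6000) {
  if (lambda_partition <= 0) {
    abort("lambda_partition must be positive", class = "oxymetr_params_error")
  }
  if (alpha_label <= 0 || alpha_label > 1) {
    abort("alpha_label must lie in (0, 1]", class = "oxymetr_params_error")
  }
  structure(list(lambda_partition = lambda_partition,
                 alpha_label = alpha_label, unit_scale = unit_scale),
            class = "asl_params")
}

as_image_array <- function(images) {
  if (is.array(images) && length(dim(images)) == 3) return(images)
  if (is.list(images)) {
    d <- dim(images[[1]])
    if (is.null(d) || !all(vapply(images, function(m)
      identical(dim(m), d), logical(1)))) {
      abort("images must share the same matrix dimensions",
            class = "oxymetr_format_error")
    }
    return(array(unlist(images), dim = c(d, length(images))))
  }
  abort("images must be a list of matrices or a 3-D array",
        class = "oxymetr_format_error")
}

#' Voxelwise T1 map from a variable-TR saturation-recovery series
#'
#' Fits `M(TR) = M0 * (1 - exp(-TR / T1))` per voxel by profiled least
#' squares: for each candidate T1 the optimal M0 is closed-form, so the
#' residual is minimised on a dense log-spaced T1 grid with parabolic
#' refinement, vectorised over all voxels. Voxels with non-positive
#' signal or whose T1 estimate falls outside `t1_bounds` are masked out
#' rather than raising an error.
#'
#' @param tr_series List of matrices (one per TR) or a 3-D array.
#' @param tr_ms Numeric TR values in milliseconds, strictly increasing,
#'   length >= 3.
#' @param t1_bounds Admissible T1 range in seconds (default `c(0.1, 5)`).
#' @param grid_n Number of T1 grid points (default 400).
#' @param mask Optional logical matrix restricting the fit to a subset of
#'   voxels (e.g. a brain or ROI mask); voxels outside are left `NA`.
#' @return List with matrices `t1_s`, `m0` (both `NA` outside valid
#'   voxels) and logical `valid`.
#' @export
fit_t1_map <- function(tr_series, tr_ms, t1_bounds = c(0.1, 5),
                       grid_n = 400, mask = NULL) {
  arr <- as_image_array(tr_series)
  n_tr <- dim(arr)[3]
  if (length(tr_ms) != n_tr || n_tr < 3 || any(diff(tr_ms) <= 0)) {
    abort("need >= 3 strictly increasing TR values matching the series",
          class = "oxymetr_format_error")
  }
  dims <- dim(arr)[1:2]
  tr_s <- tr_ms / 1000
  S <- matrix(arr, ncol = n_tr)              # voxels x TR
  use <- rep(TRUE, nrow(S))
  if (!is.null(mask)) use <- as.vector(mask)
  # voxels with no positive signal cannot be fitted
  smax <- Reduce(pmax, lapply(seq_len(n_tr), function(i) S[, i]))
  use <- use & smax > 0
  t1 <- rep(NA_real_, nrow(S)); m0 <- rep(NA_real_, nrow(S))
  if (any(use)) {
    Su <- S[use, , drop = FALSE]
    lg <- seq(log(t1_bounds[1]), log(t1_bounds[2]), length.out = grid_n)
    FG <- 1 - exp(-outer(tr_s, exp(lg), "/"))   # TR x grid
    denom <- colSums(FG^2)
    NUM <- Su %*% FG                            # voxels x grid
    Q <- sweep(NUM^2, 2, denom, "/")            # SSE reduction per grid T1
    Q[NUM <= 0] <- -Inf                         # require M0 > 0
    gstar <- max.col(Q, ties.method = "first")
    interior <- gstar > 1 & gstar < grid_n
    # parabolic refinement on the log-T1 grid
    idx <- cbind(seq_len(nrow(Q)), gstar)
    q0 <- Q[idx]
    qm <- q0; qp <- q0
    qm[interior] <- Q[cbind(which(interior), gstar[interior] - 1)]
    qp[interior] <- Q[cbind(which(interior), gstar[interior] + 1)]
    step <- lg[2] - lg[1]
    shift <- rep(0, nrow(Q))
    curv <- qm - 2 * q0 + qp
    ok_curv <- interior & is.finite(curv) & curv < 0
    shift[ok_curv] <- 0.5 * step * (qm[ok_curv] - qp[ok_curv]) / curv[ok_curv]
    t1_hat <- exp(lg[gstar] + shift)
    f_hat <- 1 - exp(-outer(t1_hat, tr_s, function(T1, tr) tr / T1))
    m0_hat <- rowSums(Su * f_hat) / rowSums(f_hat^2)
    bad <- !interior | !is.finite(t1_hat) | m0_hat <= 0 |
      t1_hat <= t1_bounds[1] | t1_hat > t1_bounds[2]
    t1_hat[bad] <- NA_real_; m0_hat[bad] <- NA_real_
    t1[use] <- t1_hat; m0[use] <- m0_hat
  }
  list(t1_s = matrix(t1, dims[1], dims[2]),
       m0 = matrix(m0, dims[1], dims[2]),
       valid = matrix(!is.na(t1), dims[1], dims[2]))
}

#' Magnetization-transfer-corrected perfusion-weighted map
#'
#' Averages the two control and the two tagged acquisitions (so MT
#' effects cancel) and differences them: `dM = mean(controls) -
#' mean(tags)`. Independent of the ordering within each pair.
#'
#' @param controls,tags Lists of two matrices each (same dimensions).
#' @return List with matrices `dM` and `m_ctrl`.
#' @export
perfusion_weighted <- function(controls, tags) {
  if (!is.list(controls) || !is.list(tags)) {
    controls <- lapply(seq_len(dim(controls)[3]), function(i) controls[, , i])
    tags <- lapply(seq_len(dim(tags)[3]), function(i) tags[, , i])
  }
  dims <- lapply(c(controls, tags), dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("control and tag images must share dimensions",
          class = "oxymetr_format_error")
  }
  mc <- Reduce(`+`, controls) / length(controls)
  mt <- Reduce(`+`, tags) / length(tags)
  list(dM = mc - mt, m_ctrl = mc)
}

#' Single-compartment CASL perfusion quantification
#'
#' `CBF = unit_scale * lambda * dM / (2 * alpha * T1 * M_ctrl)` per
#' voxel, in ml 100g^-1 min^-1. Voxels with invalid T1 or non-positive
#' control signal are set to `NA`; the number of control-signal
#' exclusions is attached as the `n_bad_ctrl` attribute.
#'
#' @param dM,m_ctrl,t1_s Matrices from [perfusion_weighted()] and
#'   [fit_t1_map()].
#' @param params An [asl_params()].
#' @return CBF matrix (ml 100g^-1 min^-1) with `NA` at masked voxels.
#' @export
quantify_cbf <- function(dM, m_ctrl, t1_s, params = asl_params()) {
  stopifnot(identical(dim(dM), dim(m_ctrl)), identical(dim(dM), dim(t1_s)))
  bad_ctrl <- !is.na(t1_s) & m_ctrl <= 0
  if (any(bad_ctrl)) {
    warn(paste0(sum(bad_ctrl), " voxel(s) with non-positive control signal",
                " masked"))
  }
  cbf <- params$unit_scale * params$lambda_partition * dM /
    (2 * params$alpha_label * t1_s * m_ctrl)
  cbf[bad_ctrl] <- NA_real_
  attr(cbf, "n_bad_ctrl") <- sum(bad_ctrl)
  cbf
}

#' ROI statistics on a perfusion map
#'
#' Arithmetic mean and sample (n-1) standard deviation over in-mask,
#' non-missing voxels. Values outside the mask never enter the
#' statistics.
#'
#' @param map Numeric matrix (may contain `NA`).
#' @param mask Logical matrix of the same dimensions.
#' @return One-row tibble: `mean`, `sd`, `n_voxels`.
#' @export
roi_statistics <- function(map, mask) {
  stopifnot(identical(dim(map), dim(mask)))
  vals <- map[mask & !is.na(map)]
  if (length(vals) == 0) {
    abort("mask contains no valid voxels", class = "oxymetr_mask_error")
  }
  tibble::tibble(mean = mean(vals), sd = sd(vals), n_voxels = length(vals))
}

#' Dual-rater ROI agreement rule
#'
#' Compares the two raters' ROI means; if the relative difference exceeds
#' the threshold (strictly over, default 5%) the analysis is flagged for
#' repetition, otherwise the primary rater's value is retained.
#'
#' @param mean_a Primary rater's ROI mean (> 0).
#' @param mean_b Second rater's ROI mean.
#' @param threshold_pct Flagging threshold in percent (default 5).
#' @return One-row tibble: `diff_pct`, `flagged`, `value_retained`
#'   (primary value, `NA` when flagged).
#' @export
rater_agreement <- function(mean_a, mean_b, threshold_pct = 5) {
  if (mean_a <= 0) {
    abort("primary ROI mean must be positive", class = "oxymetr_params_error")
  }
  d <- abs(mean_a - mean_b) / mean_a * 100
  flagged <- d > threshold_pct
  tibble::tibble(diff_pct = d, flagged = flagged,
                 value_retained = ifelse(flagged, NA_real_, mean_a))
}

#' Full per-animal ASL quantification
#'
#' T1 map from the variable-TR series, MT-corrected perfusion-weighted
#' map, single-compartment CBF quantification and cortical-ROI
#' statistics.
#'
#' @param stack An ASL stack as produced by [simulate_asl_stack()] or
#'   [read_asl_stack()]: list with `controls`, `tags`, `tr_series`,
#'   `tr_ms`, and `mask`.
#' @param params An [asl_params()].
#' @param fit_mask Optional logical matrix restricting the T1/CBF fit
#'   (defaults to all voxels).
#' @return List with `t1_map`, `m0_map`, `dM_map`, `cbf_map`, `roi`
#'   (one-row tibble `mean`, `sd`, `n_voxels`).
#' @export
analyze_asl <- function(stack, params = asl_params(), fit_mask = NULL) {
  t1fit <- fit_t1_map(stack$tr_series, stack$tr_ms, mask = fit_mask)
  pw <- perfusion_weighted(stack$controls, stack$tags)
  cbf <- quantify_cbf(pw$dM, pw$m_ctrl, t1fit$t1_s, params)
  list(t1_map = t1fit$t1_s, m0_map = t1fit$m0, dM_map = pw$dM,
       cbf_map = cbf, roi = roi_statistics(cbf, stack$mask))
}

#' Write / read an ASL stack as NIfTI with a JSON sidecar
#'
#' Stores the control, tag and variable-TR images as NIfTI files plus a
#' `sidecar.json` (TR list, geometry) and the cortical ROI mask.
#'
#' @param stack ASL stack list (see [analyze_asl()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_asl_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- stack$geometry
  pix <- c(g$fov_mm / g$matrix_size, g$fov_mm / g$matrix_size, g$slice_mm)
  wr <- function(img, name) {
    RNifti::writeNifti(RNifti::asNifti(array(img, dim = c(dim(img), 1)),
                                       pixdim = pix),
                       file.path(dir, name))
  }
  wr(stack$controls[[1]], "control_1.nii.gz")
  wr(stack$controls[[2]], "control_2.nii.gz")
  wr(stack$tags[[1]], "tag_1.nii.gz")
  wr(stack$tags[[2]], "tag_2.nii.gz")
  for (i in seq_along(stack$tr_ms)) {
    wr(stack$tr_series[[i]], sprintf("vtr_%02d.nii.gz", i))
  }
  wr(stack$mask * 1, "roi_mask.nii.gz")
  jsonlite::write_json(list(tr_ms = stack$tr_ms, geometry = g),
                       file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_asl_stack
#' @export
read_asl_stack <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  rd <- function(name) {
    a <- RNifti::readNifti(file.path(dir, name))
    matrix(a, dim(a)[1], dim(a)[2])
  }
  tr_ms <- as.numeric(side$tr_ms)
  list(controls = list(rd("control_1.nii.gz"), rd("control_2.nii.gz")),
       tags = list(rd("tag_1.nii.gz"), rd("tag_2.nii.gz")),
       tr_series = lapply(seq_along(tr_ms), function(i)
         rd(sprintf("vtr_%02d.nii.gz", i))),
       tr_ms = tr_ms, geometry = side$geometry,
       mask = rd("roi_mask.nii.gz") > 0.5)
}
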