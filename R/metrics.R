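# Segmentation evaluation: voxel confusion counts, overlap scores (F1/Dice,
# sensitivity, precision, VOE, RVD) and symmetric surface distances
# (ASSD, MSSD/Hausdorff), plus cohort aggregation.

#' Overlap metrics for one prediction/reference mask pair
#'
#' `F1 = 2TP/(2TP+FP+FN) * 100` (the Dice coefficient as a percent),
#' `TPR = TP/(TP+FN) * 100` (sensitivity), `PPV = TP/(TP+FP) * 100`
#' (precision), `VOE = (1 - |intersection|/|union|) * 100` (Jaccard error),
#' `RVD = (|pred| - |ref|)/|ref| * 100`.
#'
#' `paper_formulas = TRUE` switches TPR/PPV to the literal printed variants
#' `TPR = TP/(TP+FP)`, `PPV = TN/(TN+FP)` (kept for comparability; they
#' conflict with the names sensitivity/precision and appear to be typos).
#'
#' @param pred,ref `ct_mask` or logical arrays of equal shape.
#' @param paper_formulas use the literal printed TPR/PPV definitions.
#' @return object of class `metrics_report`: a list with counts `TP`, `FP`,
#'   `FN`, `TN` and percentages `F1`, `TPR`, `PPV`, `VOE`, `RVD`.
#' @export
overlap_metrics <- function(pred, ref, paper_formulas = FALSE) {
  p <- mask_data(pred); r <- mask_data(ref)
  if (!identical(dim(p), dim(r)))
    stop("prediction and reference masks differ in shape")
  tp <- sum(p & r); fp <- sum(p & !r); fn <- sum(!p & r)
  tn <- length(p) - tp - fp - fn
  if (sum(r) == 0) stop("reference mask is empty: RVD undefined")
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) * 100 else NA_real_
  if (paper_formulas) {
    tpr <- if (tp + fp > 0) tp / (tp + fp) * 100 else NA_real_
    ppv <- if (tn + fp > 0) tn / (tn + fp) * 100 else NA_real_
  } else {
    tpr <- if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_
    ppv <- if (tp + fp > 0) tp / (tp + fp) * 100 else NA_real_
  }
  voe <- (1 - tp / (tp + fp + fn)) * 100
  rvd <- (sum(p) - sum(r)) / sum(r) * 100
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn,
                 F1 = f1, TPR = tpr, PPV = ppv, VOE = voe, RVD = rvd),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("F1 %.2f  TPR %.2f  PPV %.2f  VOE %.2f  RVD %+.2f  (TP %d FP %d FN %d)\n",
              x$F1, x$TPR, x$PPV, x$VOE, x$RVD, x$TP, x$FP, x$FN))
  invisible(x)
}

# out[i] = m[i + by] along axis ax, FALSE beyond the grid
shift_arr <- function(m, ax, by) {
  d <- dim(m); n <- d[ax]
  out <- array(FALSE, dim = d)
  if (abs(by) >= n) return(out)
  src <- if (by > 0) (1 + by):n else 1:(n + by)
  dst <- if (by > 0) 1:(n - by) else (1 - by):n
  idx <- lapply(d, seq_len)
  isrc <- idx; isrc[[ax]] <- src
  idst <- idx; idst[[ax]] <- dst
  part <- do.call(`[`, c(list(m), isrc, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), idst, list(part)))
}

# surface voxels: mask voxels with at least one face neighbor (6-neighborhood
# in 3D, 4-neighborhood in 2D) outside the mask; grid edges count as outside.
surface_voxels <- function(m) {
  all_nb <- m
  for (ax in seq_along(dim(m)))
    all_nb <- all_nb & shift_arr(m, ax, 1) & shift_arr(m, ax, -1)
  m & !all_nb
}

#' Symmetric surface distances between two masks
#'
#' Surface voxels are mask voxels with a face neighbor outside the mask.
#' Directed distances are exact Euclidean (voxel units scaled by `spacing`)
#' from each surface voxel of one mask to the nearest surface voxel of the
#' other, computed with a distance transform.  ASSD averages both directed
#' distance sets together; MSSD is their maximum (the symmetric Hausdorff
#' distance).
#'
#' @param pred,ref `ct_mask` or logical arrays of equal shape, both
#'   non-empty.
#' @param spacing voxel size per axis in mm (recycled to the rank).
#' @return `c(ASSD = ..., MSSD = ...)` in mm.
#' @export
surface_metrics <- function(pred, ref, spacing = 1) {
  p <- mask_data(pred); r <- mask_data(ref)
  if (!identical(dim(p), dim(r)))
    stop("prediction and reference masks differ in shape")
  if (!any(p) || !any(r))
    stop("surface distances are undefined for empty masks")
  # crop to the joint bounding box: all surface voxels (sources and query
  # points alike) lie inside it, so nearest-surface distances are unchanged,
  # and the distance transforms run on a fraction of the volume
  both <- p | r
  idx <- lapply(seq_along(dim(p)), function(ax) {
    pr <- range(which(apply(both, ax, any)))
    pr[1]:pr[2]
  })
  p <- do.call(`[`, c(list(p), idx, list(drop = FALSE)))
  r <- do.call(`[`, c(list(r), idx, list(drop = FALSE)))
  d <- dim(p)
  spacing <- rep(spacing, length.out = length(d))
  sp <- surface_voxels(p); sr <- surface_voxels(r)
  dt_r <- sqrt(edt_sq_cpp(sr, d, spacing))
  dt_p <- sqrt(edt_sq_cpp(sp, d, spacing))
  d_pr <- dt_r[sp]                       # pred surface -> ref surface
  d_rp <- dt_p[sr]
  all_d <- c(d_pr, d_rp)
  c(ASSD = mean(all_d), MSSD = max(all_d))
}

#' Evaluate a cohort of prediction/reference pairs
#'
#' Metrics are computed per case and arithmetically averaged (mean of
#' per-case ratios, matching per-image averaging; note this differs from
#' ratios of summed counts).
#'
#' @param cases list of `list(pred, ref)` pairs.
#' @param spacing voxel spacing for the surface metrics.
#' @param surface compute ASSD/MSSD as well (default TRUE).
#' @param paper_formulas passed to [overlap_metrics()].
#' @return data.frame with one row per case plus a final `"mean"` row.
#' @export
evaluate_cohort <- function(cases, spacing = 1, surface = TRUE,
                            paper_formulas = FALSE) {
  if (!length(cases)) stop("evaluate_cohort needs at least one case")
  rows <- lapply(seq_along(cases), function(i) {
    om <- overlap_metrics(cases[[i]]$pred, cases[[i]]$ref, paper_formulas)
    row <- data.frame(Group = as.character(i), TP = om$TP, FP = om$FP,
                      FN = om$FN, TPR = om$TPR, PPV = om$PPV, F1 = om$F1,
                      VOE = om$VOE, RVD = om$RVD)
    if (surface) {
      sm <- surface_metrics(cases[[i]]$pred, cases[[i]]$ref, spacing)
      row$ASSD <- sm[["ASSD"]]; row$MSSD <- sm[["MSSD"]]
    }
    row
  })
  tab <- do.call(rbind, rows)
  means <- tab[1, , drop = FALSE]
  means$Group <- "mean"
  for (cn in setdiff(names(tab), "Group")) means[[cn]] <- mean(tab[[cn]])
  rbind(tab, means)
}
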