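#' Filter a gene x cell count matrix
#'
#' Retains genes detected (count >= 1) in at least `min_cells` cells and
#' cells with at least `min_features` detected genes. Both criteria are
#' evaluated on the input matrix in a single pass (no iteration), the
#' convention of standard single-cell loaders. The defaults (3 cells,
#' 1250 features) are the thresholds used for the accumbens single-cell
#' re-analysis.
#'
#' @param counts Genes x cells matrix (base or `Matrix` sparse) of
#'   non-negative integers with gene rownames.
#' @param min_cells Minimum cells a gene must be detected in.
#' @param min_features Minimum detected genes a cell must have.
#' @return Filtered matrix of the same class.
#' @export
filter_matrix <- function(counts, min_cells = 3, min_features = 1250) {
  check_counts(counts)
  detected <- counts > 0
  keep_genes <- Matrix::rowSums(detected) >= min_cells
  keep_cells <- Matrix::colSums(detected) >= min_features
  if (!any(keep_genes) || !any(keep_cells)) {
    stop("filtering removed every gene or every cell", call. = FALSE)
  }
  counts[keep_genes, keep_cells, drop = FALSE]
}

check_counts <- function(counts) {
  if (is.null(rownames(counts))) stop_field("counts", "needs gene rownames")
  if (anyDuplicated(rownames(counts))) {
    stop_field("counts", "duplicate gene names")
  }
  if (min(counts) < 0) stop_field("counts", "counts must be non-negative")
  invisible(counts)
}

#' Cells positive for a marker (single-copy rule)
#'
#' A cell is marker-positive iff it has at least one count of the gene —
#' a raw-count property, unaffected by any (zero-preserving)
#' normalization.
#'
#' @param counts Genes x cells count matrix with gene rownames.
#' @param marker Gene name.
#' @return Character vector of positive cell ids (or column indices as
#'   strings when the matrix has no colnames).
#' @export
positive_cells <- function(counts, marker) {
  if (!marker %in% rownames(counts)) {
    near <- utils::head(agrep(marker, rownames(counts), value = TRUE,
                              ignore.case = TRUE), 5L)
    stop_field("marker", sprintf("'%s' not found%s", marker,
                                 if (length(near)) {
                                   paste0("; near matches: ",
                                          paste(near, collapse = ", "))
                                 } else ""))
  }
  ids <- colnames(counts)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(counts)))
  ids[as.numeric(counts[marker, ]) >= 1]
}

#' Marker co-expression percentage
#'
#' `100 * |A+ intersect B+| / |denominator set|`, where the denominator is
#' the positive set of marker `a` or `b`. Both orientations are useful:
#' the fraction of receptor-positive cells expressing the probe, and the
#' fraction of probe-positive cells expressing the receptor.
#'
#' @param counts Genes x cells count matrix.
#' @param marker_a,marker_b Gene names.
#' @param denominator `"a"` or `"b"`: which marker's positive set divides.
#' @return Percentage in `[0, 100]`.
#' @export
coexpression_fraction <- function(counts, marker_a, marker_b,
                                  denominator = c("a", "b")) {
  denominator <- match.arg(denominator)
  pa <- positive_cells(counts, marker_a)
  pb <- positive_cells(counts, marker_b)
  denom <- if (denominator == "a") pa else pb
  if (!length(denom)) {
    stop_field("denominator", "the denominator marker has no positive cells")
  }
  100 * length(intersect(pa, pb)) / length(denom)
}

#' Probe positivity percentages from a classified-cell table
#'
#' For each group (by default region x rostro-caudal position): the
#' percentage of Drd1+ cells that are probe+ and of Drd2+ cells that are
#' probe+. Percentages are computed per section, averaged within animal,
#' then across animals, so animals contribute equally regardless of
#' section or cell counts. Groups with no receptor-positive cells in any
#' section are flagged undefined (`NaN`).
#'
#' @param cells Data frame with columns `animal`, `section`, `roi`,
#'   `axis_position`, `drd1_pos`, `drd2_pos`, `probe_pos` (logical flags).
#' @param group_by Grouping columns, default `c("roi", "axis_position")`.
#' @return Data frame: grouping columns, `pct_probe_in_drd1`,
#'   `pct_probe_in_drd2`, `n_animals`.
#' @export
fish_proportions <- function(cells, group_by = c("roi", "axis_position")) {
  stopifnot(is.data.frame(cells),
            all(c("animal", "section", group_by,
                  "drd1_pos", "drd2_pos", "probe_pos") %in% names(cells)))
  if (!nrow(cells)) stop_field("cells", "table is empty")
  for (fl in c("drd1_pos", "drd2_pos", "probe_pos")) {
    if (!is.logical(cells[[fl]])) stop_field(fl, "must be logical")
  }
  key <- interaction(cells[group_by], drop = TRUE, sep = "|")
  groups <- split(cells, key)
  section_pct <- function(d, receptor) {
    pos <- d[[receptor]]
    if (!any(pos)) return(NA_real_)
    100 * sum(pos & d$probe_pos) / sum(pos)
  }
  res <- lapply(groups, function(g) {
    per_animal <- vapply(split(g, g$animal), function(ga) {
      sec <- split(ga, ga$section)
      c(d1 = mean(vapply(sec, section_pct, numeric(1), "drd1_pos"),
                  na.rm = TRUE),
        d2 = mean(vapply(sec, section_pct, numeric(1), "drd2_pos"),
                  na.rm = TRUE))
    }, numeric(2))
    grp <- g[1L, group_by, drop = FALSE]
    grp$pct_probe_in_drd1 <- mean(per_animal["d1", ], na.rm = TRUE)
    grp$pct_probe_in_drd2 <- mean(per_animal["d2", ], na.rm = TRUE)
    grp$n_animals <- ncol(per_animal)
    grp
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Background-corrected optical density
#'
#' Per hemisphere, `corrected = roi_mean - background_mean` (the
#' background square is taken in the anterior commissure); the reported
#' value averages the two hemisphere measures. Negative corrected values
#' are preserved (no clipping). With a single hemisphere the value is
#' returned with `single_hemisphere = TRUE` and a warning.
#'
#' @param roi_means One or two hemisphere ROI square means (a.u.).
#' @param background_mean Background square mean (a.u.); if two values are
#'   given they are averaged first.
#' @return List: `corrected` (per hemisphere), `value` (reported mean),
#'   `single_hemisphere`.
#' @export
optical_density <- function(roi_means, background_mean) {
  if (!length(roi_means) || length(roi_means) > 2L ||
      any(!is.finite(roi_means))) {
    stop_field("roi_means", "needs one or two finite hemisphere values")
  }
  if (any(!is.finite(background_mean))) {
    stop_field("background_mean", "must be finite")
  }
  bg <- mean(background_mean)
  corrected <- roi_means - bg
  single <- length(roi_means) == 1L
  if (single) warning("single hemisphere measurement; value not averaged")
  list(corrected = corrected, value = mean(corrected),
       single_hemisphere = single)
}
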