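# Correlation of bioactivity peaks with MS features by retention time,
# in-source fragment / adduct annotation among co-eluting bioactive features,
# and marking of bioactive nodes in the molecular network.

#' Neutral-delta table for in-source relations
#'
#' Exact mass deltas (Da) of the relations commonly seen among co-eluting
#' bioactive features of glycosylated natural products:
#' water loss (H2O, 18.010565), deoxysugar losses (C6H10O2, 114.068080;
#' C6H10O3, 130.062995) and the acetonitrile solvent adduct
#' (MeCN = C2H3N, +41.026549). User-extensible: pass extra named deltas.
#'
#' @param ... Additional named deltas in Da.
#' @return Named numeric vector of positive mass deltas.
#' @export
neutral_delta_table <- function(...) {
  base <- c(H2O = monoisotopic_mass("H2O"),
            C6H10O2 = monoisotopic_mass("C6H10O2"),
            C6H10O3 = monoisotopic_mass("C6H10O3"),
            MeCN = monoisotopic_mass("C2H3N"))
  extra <- c(...)
  if (length(extra)) {
    stopifnot(!is.null(names(extra)), all(nzchar(names(extra))), all(extra > 0))
    base <- c(base, extra)
  }
  base
}

#' Assign MS features to bioactivity peaks by retention time
#'
#' A feature belongs to a bioactivity peak iff its apex RT lies inside the
#' peak's (delay-corrected) window widened by `rt_tolerance` on both sides.
#' Features may map to several overlapping peaks. Peaks with no features are
#' still reported (with an empty feature set).
#'
#' @param features Feature data frame (columns `id`, `mz`, `rt`, `height`).
#' @param peaks Bioactivity peak data frame from
#'   [detect_bioactivity_peaks()], on the same (delay-corrected) time axis
#'   as the features.
#' @param rt_tolerance Window widening in minutes; default 0.1 (one 6-s
#'   fraction).
#' @return An object of class `bioactive_assignments`: list with `table`
#'   (data frame `peak_id`, `feature_id`, `mz`, `rt`, `height`, sorted by
#'   peak then descending height) and `peaks` (the input peaks).
#' @export
map_bioactive_features <- function(features, peaks, rt_tolerance = 0.1) {
  tab <- data.frame(peak_id = integer(0), feature_id = integer(0),
                    mz = numeric(0), rt = numeric(0), height = numeric(0))
  for (k in seq_len(nrow(peaks))) {
    lo <- peaks$start_time[k] - rt_tolerance
    hi <- peaks$end_time[k] + rt_tolerance
    hit <- which(features$rt >= lo & features$rt <= hi)
    if (length(hit)) {
      hit <- hit[order(-features$height[hit])]
      tab <- rbind(tab, data.frame(peak_id = peaks$peak_id[k],
                                   feature_id = features$id[hit],
                                   mz = features$mz[hit],
                                   rt = features$rt[hit],
                                   height = features$height[hit]))
    }
  }
  rownames(tab) <- NULL
  structure(list(table = tab, peaks = peaks, rt_tolerance = rt_tolerance),
            class = "bioactive_assignments")
}

#' @export
print.bioactive_assignments <- function(x, ...) {
  cat("<bioactive assignments> ", nrow(x$peaks), " peaks, ",
      length(unique(x$table$feature_id)), " assigned features\n", sep = "")
  invisible(x)
}

#' Annotate in-source fragment / adduct relations within bioactivity peaks
#'
#' For every ordered pair of features assigned to the same peak, labels the
#' relation whose neutral delta (or sum of two deltas, for chains such as
#' sugar loss followed by water loss) matches the m/z difference within
#' `mz_tol`. The higher-mass feature is reported as the parent.
#'
#' @param assignments A `bioactive_assignments` object.
#' @param deltas Named delta table from [neutral_delta_table()].
#' @param mz_tol Absolute tolerance in Da (default 0.005; printed deltas in
#'   the validation chemistry deviate from exact by up to ~2 mDa).
#' @param chains Allow sums of two deltas? (default TRUE).
#' @return Data frame `peak_id`, `parent_id`, `child_id`, `parent_mz`,
#'   `child_mz`, `delta`, `relation` (delta labels joined by `+` for
#'   chains).
#' @export
annotate_insource_relations <- function(assignments, deltas = neutral_delta_table(),
                                        mz_tol = 0.005, chains = TRUE) {
  stopifnot(inherits(assignments, "bioactive_assignments"))
  lab <- names(deltas)
  combo_d <- deltas
  combo_l <- lab
  if (chains && length(deltas) > 1L) {
    for (i in seq_along(deltas)) for (j in i:length(deltas)) {
      combo_d <- c(combo_d, deltas[[i]] + deltas[[j]])
      combo_l <- c(combo_l, paste(lab[i], lab[j], sep = "+"))
    }
  }
  out <- data.frame(peak_id = integer(0), parent_id = integer(0),
                    child_id = integer(0), parent_mz = numeric(0),
                    child_mz = numeric(0), delta = numeric(0),
                    relation = character(0))
  tab <- assignments$table
  for (pk in unique(tab$peak_id)) {
    rows <- tab[tab$peak_id == pk, , drop = FALSE]
    if (nrow(rows) < 2L) next
    for (i in seq_len(nrow(rows) - 1L)) for (j in (i + 1L):nrow(rows)) {
      hi <- if (rows$mz[i] >= rows$mz[j]) i else j
      lo <- if (hi == i) j else i
      d <- rows$mz[hi] - rows$mz[lo]
      m <- which(abs(combo_d - d) <= mz_tol)
      if (length(m)) {
        m <- m[which.min(abs(combo_d[m] - d))]
        out <- rbind(out, data.frame(
          peak_id = pk, parent_id = rows$feature_id[hi],
          child_id = rows$feature_id[lo], parent_mz = rows$mz[hi],
          child_mz = rows$mz[lo], delta = d, relation = combo_l[m]))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Mark bioactive nodes in a molecular network
#'
#' Sets the `bioactive` flag on every network node whose id appears in the
#' assignments; other nodes are untouched. Idempotent. Assignments that
#' reference unknown node ids raise a warning and are skipped.
#'
#' @param net A `molecular_network`.
#' @param assignments A `bioactive_assignments` object (or an integer vector
#'   of feature ids).
#' @return The network with updated `bioactive` flags.
#' @export
mark_network <- function(net, assignments) {
  ids <- if (inherits(assignments, "bioactive_assignments"))
    unique(assignments$table$feature_id) else unique(as.integer(assignments))
  unknown <- setdiff(ids, net$nodes$id)
  if (length(unknown)) {
    warning("skipping assignment(s) for unknown node id(s): ",
            paste(unknown, collapse = ", "))
    ids <- setdiff(ids, unknown)
  }
  net$nodes$bioactive[net$nodes$id %in% ids] <- TRUE
  net
}

#' Write the bioactive assignment report as CSV
#'
#' One row per (peak, feature) pair with the peak window, feature m/z, RT,
#' height and any in-source relation labels attached to the feature within
#' that peak; peaks without features are written with empty feature fields.
#'
#' @param assignments A `bioactive_assignments` object.
#' @param relations Optional relation data frame from
#'   [annotate_insource_relations()].
#' @param path Output path.
#' @export
write_assignment_csv <- function(assignments, path, relations = NULL) {
  pk <- assignments$peaks
  tab <- assignments$table
  rows <- list()
  for (k in seq_len(nrow(pk))) {
    sub <- tab[tab$peak_id == pk$peak_id[k], , drop = FALSE]
    if (nrow(sub) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = pk$peak_id[k], peak_start = pk$start_time[k],
        peak_end = pk$end_time[k], feature_id = NA_integer_,
        mz = NA_real_, rt = NA_real_, height = NA_real_,
        relation_labels = "")
    } else {
      labs <- vapply(sub$feature_id, function(fid) {
        if (is.null(relations) || nrow(relations) == 0L) return("")
        r <- relations[relations$peak_id == pk$peak_id[k] &
                         (relations$parent_id == fid | relations$child_id == fid), ]
        if (nrow(r) == 0L) return("")
        paste(unique(ifelse(r$parent_id == fid,
                            paste0("parent:", r$relation),
                            paste0("child:", r$relation))), collapse = ";")
      }, character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = pk$peak_id[k], peak_start = pk$start_time[k],
        peak_end = pk$end_time[k], feature_id = sub$feature_id,
        mz = sub$mz, rt = sub$rt, height = sub$height,
        relation_labels = labs)
    }
  }
  out <- do.call(rbind, rows)
  out$peak_start <- sprintf("%.4f", out$peak_start)
  out$peak_end <- sprintf("%.4f", out$peak_end)
  out$mz <- ifelse(is.na(out$mz), "", sprintf("%.4f", out$mz))
  out$rt <- ifelse(is.na(out$rt), "", sprintf("%.4f", out$rt))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
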