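#' Two-level cohort aggregation
#'
#' Aggregates per-nucleus measurements to embryo means, then reports
#' the cohort mean and the standard deviation between embryo
#' replicates, per grouping cell. The sd is \code{NA} when fewer than
#' two embryos contribute; \code{n} (embryo count) is always reported.
#' The result is invariant to the ordering of the input rows.
#'
#' @param df data.frame with an \code{embryo_id} column, grouping
#'   columns, and one \code{value} column.
#' @param groupBy character vector of grouping column names (e.g.
#'   \code{c("gene", "cycle", "frame")}).
#' @param valueCol name of the value column.
#' @return data.frame: grouping columns, mean, sd, n.
#' @export
aggregateCohort <- function(df, groupBy, valueCol = "value") {
  stopifnot("embryo_id" %in% names(df), valueCol %in% names(df))
  # nuclei -> embryo
  emb <- stats::aggregate(df[[valueCol]],
                          by = df[c("embryo_id", groupBy)],
                          FUN = mean, na.rm = TRUE)
  names(emb)[ncol(emb)] <- "value"
  # embryo -> cohort
  agg <- function(v) c(mean = mean(v), sd = if (length(v) >= 2L)
    stats::sd(v) else NA_real_, n = length(v))
  out <- stats::aggregate(emb$value, by = emb[groupBy], FUN = agg)
  stats_mat <- out$x
  out$x <- NULL
  out$mean <- stats_mat[, "mean"]
  out$sd <- stats_mat[, "sd"]
  out$n <- as.integer(stats_mat[, "n"])
  ord <- do.call(order, out[groupBy])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mid-interphase frame selection
#'
#' The "middle of interphase" window used for distribution box plots is
#' defined as the middle third of the observed cycle.
#'
#' @param frames integer vector of frame indices covering one cycle.
#' @return logical vector marking frames in the middle third.
#' @export
midInterphase <- function(frames) {
  lo <- min(frames); hi <- max(frames)
  span <- hi - lo
  frames >= lo + span / 3 & frames <= hi - span / 3
}

#' Render a deterministic report from cohort summaries
#'
#' Writes summary tables (CSV), simple figures (survival curves, time
#' courses, box plots, scatter panels; PNG), and a plain-text index
#' listing every emitted file with the config hash. Identical inputs
#' produce byte-identical tables; an empty cohort produces explicit
#' "no data" placeholders and still succeeds.
#'
#' @param summaries named list of data.frames (e.g. from
#'   [aggregateCohort()], [survivalCurve()], [groupCompare()]).
#' @param outDir output directory.
#' @param configHash optional config fingerprint embedded in the index.
#' @return invisibly, the manifest data.frame (file, kind).
#' @export
renderReport <- function(summaries, outDir, configHash = NA_character_) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (nm in names(summaries)) {
    df <- summaries[[nm]]
    p <- file.path(outDir, paste0(nm, ".csv"))
    if (is.null(df) || nrow(df) == 0L) {
      writeLines("no data", file.path(outDir, paste0(nm, ".txt")))
      manifest[[length(manifest) + 1L]] <-
        data.frame(file = paste0(nm, ".txt"), kind = "placeholder")
      next
    }
    utils::write.csv(format(df, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     p, row.names = FALSE, quote = TRUE)
    manifest[[length(manifest) + 1L]] <-
      data.frame(file = paste0(nm, ".csv"), kind = "table")
    num <- names(df)[vapply(df, is.numeric, logical(1))]
    if (length(num) >= 2L) {
      fp <- file.path(outDir, paste0(nm, ".png"))
      grDevices::png(fp, width = 640, height = 480)
      plot(df[[num[1]]], df[[num[2]]], xlab = num[1], ylab = num[2],
           main = nm, type = if (nm %in% c("survival", "timecourse"))
             "s" else "p", pch = 16)
      grDevices::dev.off()
      manifest[[length(manifest) + 1L]] <-
        data.frame(file = paste0(nm, ".png"), kind = "figure")
    }
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(file = character(0), kind = character(0))
  idx <- c(paste("config hash:", configHash),
           paste(manifest$kind, manifest$file, sep = ": "))
  writeLines(idx, file.path(outDir, "index.txt"))
  invisible(manifest)
}
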