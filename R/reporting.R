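#' Per-cell morphology summary
#'
#' Counts and count-based percentages of the four classes for one cell,
#' plus the per-object (extension, area) records of filaments and rods.
#' Because the choice of denominator is a convention, area-weighted
#' percentages are computed alongside the count-based ones. A cell with no
#' retained objects has undefined (NA) percentages, not zeros.
#'
#' @param classified Feature table with a \code{class} column, as returned
#'   by \code{\link{classify_cell}}.
#' @param cell_id Cell identifier; defaults to the table's own cell_id.
#' @return An object of class \code{cell_summary}: a list with
#'   \code{cell_id}, \code{n_objects}, \code{counts}, \code{percent},
#'   \code{percent_area}, \code{filament_records}, \code{rod_records}.
#' @export
summarize_cell <- function(classified, cell_id = NULL) {
  if (is.null(cell_id))
    cell_id <- if (nrow(classified) > 0L) classified$cell_id[1L] else "cell"
  stopifnot(all(classified$class %in% MORPH_CLASSES))
  n <- nrow(classified)
  counts <- vapply(MORPH_CLASSES,
                   function(k) sum(classified$class == k), integer(1L))
  if (n > 0L) {
    percent <- 100 * counts / n
    areas <- vapply(MORPH_CLASSES,
                    function(k) sum(classified$A[classified$class == k]),
                    numeric(1L))
    percent_area <- 100 * areas / sum(classified$A)
  } else {
    percent <- stats::setNames(rep(NA_real_, 4L), MORPH_CLASSES)
    percent_area <- percent
  }
  rec <- function(k) {
    d <- classified[classified$class == k, c("label", "E", "A"), drop = FALSE]
    rownames(d) <- NULL
    d
  }
  structure(list(cell_id = cell_id, n_objects = n, counts = counts,
                 percent = percent, percent_area = percent_area,
                 filament_records = rec("filament"),
                 rod_records = rec("rod")),
            class = "cell_summary")
}

#' @export
print.cell_summary <- function(x, ...) {
  cat(sprintf("<cell_summary> %s: %d object(s)\n", x$cell_id, x$n_objects))
  if (x$n_objects > 0L)
    cat(paste(sprintf("  %s: %d (%.1f%%)", names(x$counts), x$counts,
                      x$percent), collapse = "\n"), "\n")
  invisible(x)
}

#' Aggregate per-cell percentages into group statistics
#'
#' Cell-level averaging: the unweighted mean (and standard deviation and n)
#' of the per-cell class percentages within each group, mirroring averaging
#' over clones of a cell line. Cells with no retained objects have
#' undefined percentages and are excluded with a message; a group left with
#' no cells is omitted with a warning. A single-cell group reports
#' \code{NA} standard deviations.
#'
#' @param summaries List of \code{cell_summary} objects.
#' @param group_of Named character vector mapping cell_id to group.
#' @return A data frame with one row per (group, class): columns
#'   \code{group}, \code{class}, \code{mean_percent}, \code{sd_percent},
#'   \code{n_cells}.
#' @export
aggregate_cells <- function(summaries, group_of) {
  ids <- vapply(summaries, `[[`, character(1L), "cell_id")
  if (!all(ids %in% names(group_of)))
    stop("no group mapping for cell(s): ",
         paste(setdiff(ids, names(group_of)), collapse = ", "))
  empty <- vapply(summaries, function(s) s$n_objects == 0L, logical(1L))
  if (any(empty)) {
    message("excluding ", sum(empty), " cell(s) with no retained objects: ",
            paste(ids[empty], collapse = ", "))
    summaries <- summaries[!empty]
    ids <- ids[!empty]
  }
  groups <- unique(unname(group_of))
  out <- list()
  for (g in groups) {
    members <- summaries[group_of[ids] == g]
    if (length(members) == 0L) {
      warning("group '", g, "' has no cells with objects; omitted")
      next
    }
    pc <- do.call(rbind, lapply(members, `[[`, "percent"))
    out[[length(out) + 1L]] <- data.frame(
      group = g,
      class = MORPH_CLASSES,
      mean_percent = colMeans(pc),
      sd_percent = if (nrow(pc) > 1L) apply(pc, 2L, stats::sd) else NA_real_,
      n_cells = nrow(pc),
      row.names = NULL
    )
  }
  if (length(out) == 0L)
    return(data.frame(group = character(), class = character(),
                      mean_percent = numeric(), sd_percent = numeric(),
                      n_cells = integer()))
  do.call(rbind, out)
}

#' Flatten cell summaries to a one-row-per-cell table
#'
#' @param summaries List of \code{cell_summary} objects.
#' @return Data frame with cell_id, n_objects and the count, count-based
#'   percentage and area-based percentage of each class.
#' @export
cells_table <- function(summaries) {
  rows <- lapply(summaries, function(s) {
    d <- data.frame(cell_id = s$cell_id, n_objects = s$n_objects)
    for (k in MORPH_CLASSES) {
      d[[paste0("n_", k)]] <- s$counts[[k]]
      d[[paste0("pct_", k)]] <- s$percent[[k]]
      d[[paste0("pct_area_", k)]] <- s$percent_area[[k]]
    }
    d
  })
  do.call(rbind, rows)
}

# CSV writers with a units header comment line; read back with
# read.csv(..., comment.char = "#").
write_csv_units <- function(df, path, units_line) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", units_line), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write the three standard result tables
#'
#' \code{objects.csv} (one row per object with class and features),
#' \code{cells.csv} (one row per cell) and \code{groups.csv} (one row per
#' group and class). Units are documented in a leading comment line of
#' each file.
#'
#' @param objects Combined classified feature table (all cells).
#' @param summaries List of \code{cell_summary} objects.
#' @param groups Data frame from \code{\link{aggregate_cells}}, or NULL to
#'   skip.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the written paths, invisibly.
#' @export
write_results <- function(objects, summaries, groups, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0L)
  p <- file.path(out_dir, "objects.csv")
  cols <- c("cell_id", "label", "class", "A", "P", "AR", "C", "S", "MLE",
            "E", "r_eq")
  write_csv_units(objects[, intersect(cols, names(objects)), drop = FALSE], p,
                  "A,P,MLE,E,r_eq in um^2/um; AR,C,S dimensionless")
  paths <- c(paths, p)
  p <- file.path(out_dir, "cells.csv")
  write_csv_units(cells_table(summaries), p,
                  "pct_* are percentages of retained objects (count- and area-based)")
  paths <- c(paths, p)
  if (!is.null(groups)) {
    p <- file.path(out_dir, "groups.csv")
    write_csv_units(groups, p,
                    "mean/sd of per-cell count-based class percentages")
    paths <- c(paths, p)
  }
  invisible(paths)
}
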