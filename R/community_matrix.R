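#' Construct a community matrix of per-host species counts
#'
#' The universal input of the package: a hosts-by-species table of
#' nonnegative integer counts (CFU per individual host) together with a
#' host-lineage label per row. Row sums (total CFU per host) are computed
#' and stored on construction.
#'
#' @param counts Numeric matrix or data frame, hosts in rows and species in
#'   columns; all cells must be nonnegative integers. Column names are the
#'   species labels; row names (if absent, `host_ids`) identify hosts.
#' @param lineage Character vector, one lineage label per host
#'   (e.g. `"N2"`, `"daf-2"`). Recycled if length 1.
#' @param host_ids Optional character vector of unique host identifiers;
#'   defaults to the row names of `counts` or `host_1 ... host_n`.
#' @return An object of class `community_matrix`: a list with elements
#'   `counts` (integer matrix), `lineage` (character), `host_ids`,
#'   `species_names`, and `totals` (per-host row sums).
#' @examples
#' m <- community_matrix(rbind(c(1, 2, 3), c(0, 0, 4)), lineage = "N2")
#' m$totals  # 6 4
#' @export
community_matrix <- function(counts, lineage, host_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("counts must be numeric")
  }
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing count at row %d, column %d", bad[1L], bad[2L]))
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at row %d, column %d", bad[1L], bad[2L]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at row %d, column %d", bad[1L], bad[2L]))
  }
  storage.mode(counts) <- "integer"
  n <- nrow(counts)
  if (is.null(host_ids)) {
    host_ids <- rownames(counts)
    if (is.null(host_ids)) host_ids <- paste0("host_", seq_len(n))
  }
  if (anyDuplicated(host_ids)) stop("duplicate host ids")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sp_", seq_len(ncol(counts)))
  }
  if (anyDuplicated(colnames(counts))) stop("duplicate species names")
  if (length(lineage) == 1L) lineage <- rep(lineage, n)
  if (length(lineage) != n) stop("lineage must have one label per host")
  if (n > 0L) rownames(counts) <- host_ids
  structure(
    list(
      counts = counts,
      lineage = as.character(lineage),
      host_ids = as.character(host_ids),
      species_names = colnames(counts),
      totals = as.integer(rowSums(counts))
    ),
    class = "community_matrix"
  )
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf(
    "community_matrix: %d hosts x %d species; lineages: %s\n",
    nrow(x$counts), ncol(x$counts),
    paste(sprintf("%s (%d)", names(table(x$lineage)), table(x$lineage)),
          collapse = ", ")
  ))
  cat(sprintf("total CFU/host: median %s, range %s-%s\n",
              format(stats::median(x$totals)), format(min(x$totals)),
              format(max(x$totals))))
  invisible(x)
}

#' @export
dim.community_matrix <- function(x) dim(x$counts)

#' Subset a community matrix by hosts and/or species
#'
#' @param x A `community_matrix`.
#' @param hosts,species Index vectors (logical, integer, or names).
#' @return A `community_matrix` with totals recomputed.
#' @export
subset_community <- function(x, hosts = NULL, species = NULL) {
  stopifnot(inherits(x, "community_matrix"))
  counts <- x$counts
  lineage <- x$lineage
  if (!is.null(hosts)) {
    idx <- if (is.character(hosts)) match(hosts, x$host_ids) else
      seq_len(nrow(counts))[hosts]
    counts <- counts[idx, , drop = FALSE]
    lineage <- lineage[idx]
  }
  if (!is.null(species)) {
    counts <- counts[, species, drop = FALSE]
  }
  community_matrix(counts, lineage)
}

#' Read a per-host species count table
#'
#' Expects one header row naming the columns: a host-id column, a lineage
#' column, then one column per species with integer CFU counts.
#'
#' @param path File to read.
#' @param format `"csv"`, `"tsv"`, or `"xlsx"`. XLSX reading (used for
#'   published supplementary community-composition workbooks) requires the
#'   readxl package and targets the first sheet unless `sheet` is given.
#' @param host_col,lineage_col Column names (case-sensitive) holding host id
#'   and lineage; all remaining columns are taken as species.
#' @param sheet Sheet name or index for `format = "xlsx"`.
#' @return A [community_matrix()].
#' @export
read_count_table <- function(path, format = c("csv", "tsv", "xlsx"),
                             host_col = "host_id", lineage_col = "lineage",
                             sheet = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(switch(format,
    csv = utils::read.csv(path, check.names = FALSE),
    tsv = utils::read.delim(path, check.names = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("xlsx input requires the readxl package")
      }
      as.data.frame(readxl::read_excel(path, sheet = sheet),
                    check.names = FALSE)
    }
  ), error = function(e) stop("parse error reading ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L) stop("parse error: empty table in ", path)
  if (!(host_col %in% names(df))) stop("malformed header: no column '", host_col, "'")
  if (!(lineage_col %in% names(df))) stop("malformed header: no column '", lineage_col, "'")
  sp_cols <- setdiff(names(df), c(host_col, lineage_col))
  if (length(sp_cols) == 0L) stop("malformed header: no species columns")
  counts <- as.matrix(df[, sp_cols, drop = FALSE])
  if (!is.numeric(counts)) {
    bad <- sp_cols[!vapply(df[sp_cols], is.numeric, logical(1L))][1L]
    stop("parse error: non-numeric counts in column '", bad, "'")
  }
  for (j in seq_along(sp_cols)) {
    cj <- counts[, j]
    if (anyNA(cj) || any(cj < 0) || any(cj != round(cj))) {
      i <- which(is.na(cj) | cj < 0 | cj != round(cj))[1L]
      stop(sprintf("parse error: invalid count at row %d, column '%s'",
                   i, sp_cols[j]))
    }
  }
  community_matrix(counts, lineage = as.character(df[[lineage_col]]),
                   host_ids = as.character(df[[host_col]]))
}

#' Write a community matrix as a delimited count table
#'
#' Inverse of [read_count_table()]: `host_id`, `lineage`, then species
#' columns, UTF-8, unquoted numerics.
#'
#' @param m A `community_matrix`.
#' @param path Output file.
#' @param format `"csv"` or `"tsv"`.
#' @export
write_count_table <- function(m, path, format = c("csv", "tsv")) {
  stopifnot(inherits(m, "community_matrix"))
  format <- match.arg(format)
  df <- data.frame(host_id = m$host_ids, lineage = m$lineage,
                   m$counts, check.names = FALSE)
  utils::write.table(df, path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-lineage host filtering policy
#'
#' Encodes the count-quality filtering applied before analysis: hosts whose
#' total CFU falls below their lineage's threshold are removed (low plate
#' counts carry large relative error). The conventional thresholds are
#' 100 CFU/host for the weakly colonized daf-2 lineage and 1,000 CFU/host
#' for all other lineages.
#'
#' @param min_total_by_lineage Named numeric vector mapping lineage labels
#'   to minimum-total thresholds.
#' @param default_min_total Threshold for lineages not listed.
#' @param species_to_drop_by_lineage Optional named list mapping lineage
#'   labels to species to remove before analysis.
#' @return An object of class `lineage_filter_policy`.
#' @examples
#' lineage_filter_policy(c("daf-2" = 100), default_min_total = 1000)
#' @export
lineage_filter_policy <- function(min_total_by_lineage = c("daf-2" = 100),
                                  default_min_total = 1000,
                                  species_to_drop_by_lineage = list()) {
  thr <- c(unlist(min_total_by_lineage), .default = default_min_total)
  if (any(thr < 0)) stop("thresholds must be >= 0")
  structure(
    list(min_total_by_lineage = min_total_by_lineage,
         default_min_total = default_min_total,
         species_to_drop_by_lineage = species_to_drop_by_lineage),
    class = "lineage_filter_policy"
  )
}

#' Remove hosts with low total counts
#'
#' Keeps exactly the hosts whose total CFU is at or above their lineage's
#' threshold; host order is preserved. The number of hosts removed per
#' lineage is reported as a message and attached as attribute `"removed"`.
#' Host filtering is applied to the full-community totals, before any
#' species are dropped.
#'
#' @param m A `community_matrix`.
#' @param policy A [lineage_filter_policy()].
#' @return Filtered `community_matrix` (possibly with zero hosts, with a
#'   warning).
#' @export
filter_low_count_hosts <- function(m, policy = lineage_filter_policy()) {
  stopifnot(inherits(m, "community_matrix"),
            inherits(policy, "lineage_filter_policy"))
  by_lin <- policy$min_total_by_lineage
  thr <- vapply(m$lineage, function(l) {
    i <- match(l, names(by_lin))
    if (is.na(i)) policy$default_min_total else unname(by_lin[i])
  }, numeric(1L), USE.NAMES = FALSE)
  keep <- m$totals >= thr
  removed <- table(factor(m$lineage[!keep], levels = unique(m$lineage)))
  for (l in names(removed)) {
    if (removed[[l]] > 0L) {
      message(sprintf("filter_low_count_hosts: removed %d %s host(s) below threshold",
                      removed[[l]], l))
    }
  }
  if (!any(keep)) warning("all hosts removed by filtering")
  out <- subset_community(m, hosts = keep)
  attr(out, "removed") <- removed
  out
}

#' Drop species columns from a community matrix
#'
#' Removes the named species and recomputes per-host totals from the
#' remaining columns (used e.g. to exclude a sporadically detected species
#' from drop-down assay tables).
#'
#' @param m A `community_matrix`.
#' @param species Character vector of species labels to remove; every label
#'   must be present.
#' @return `community_matrix` without those columns.
#' @export
drop_species <- function(m, species) {
  stopifnot(inherits(m, "community_matrix"))
  if (length(species) == 0L) return(m)
  unknown <- setdiff(species, m$species_names)
  if (length(unknown) > 0L) {
    stop("unknown species: ", paste(unknown, collapse = ", "))
  }
  subset_community(m, species = setdiff(m$species_names, species))
}

#' Apply a full filtering policy (hosts first, then species)
#'
#' Host filtering on full-community totals precedes species dropping, so a
#' host's retention never depends on which species are later discarded.
#' Because species-to-drop lists are per lineage (different lineages may
#' shed different species), the result is a named list of per-lineage
#' `community_matrix` objects when any drops are configured, and a single
#' `community_matrix` otherwise.
#'
#' @inheritParams filter_low_count_hosts
#' @return Filtered `community_matrix`, or a named list of them (one per
#'   lineage) when `species_to_drop_by_lineage` is non-empty.
#' @export
apply_filter_policy <- function(m, policy = lineage_filter_policy()) {
  out <- filter_low_count_hosts(m, policy)
  drops <- policy$species_to_drop_by_lineage
  if (length(drops) == 0L) return(out)
  lins <- unique(out$lineage)
  pieces <- lapply(lins, function(l) {
    sub <- subset_community(out, hosts = out$lineage == l)
    if (!is.null(drops[[l]])) drop_species(sub, drops[[l]]) else sub
  })
  names(pieces) <- lins
  pieces
}
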