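#' Basal area of a stem from its diameter at breast height
#'
#' Standard forestry conversion: `pi * (dbh / 200)^2` gives the cross-sectional
#' area in square metres of a stem of diameter `dbh_cm` centimetres.
#'
#' @param dbh_cm stem diameter at breast height, cm; strictly positive.
#' @return Basal area in m^2.
#' @export
basal_area_from_dbh <- function(dbh_cm) {
  if (any(!is.finite(dbh_cm)) || any(dbh_cm <= 0))
    stop("dbh_cm must be finite and strictly positive")
  pi * (dbh_cm / 200)^2
}

#' Species recoding rule
#'
#' Inventory species lists need cleaning before clustering: varieties get
#' merged into one code, unreliable generic labels get dropped, and wide-ranging
#' species can be split into regional variants (e.g. coastal vs interior
#' Douglas-fir) by a plain region-code match.
#'
#' @param kind one of `"merge"`, `"drop"`, `"regional_split"`.
#' @param source_codes species codes the rule applies to.
#' @param target_code replacement code (`merge` only).
#' @param region_map named character vector mapping region codes to target
#'   species codes (`regional_split` only).
#' @param default_target target for regions absent from `region_map`
#'   (`regional_split` only).
#' @return A list of class `recoding_rule`.
#' @export
recoding_rule <- function(kind, source_codes, target_code = NULL,
                          region_map = NULL, default_target = NULL) {
  kind <- match.arg(kind, c("merge", "drop", "regional_split"))
  if (kind == "merge" && is.null(target_code))
    stop("merge rules need a target_code")
  if (kind %in% c("merge", "drop") && !is.null(region_map))
    stop("merge/drop rules must not carry a region_map")
  if (kind == "regional_split" &&
      (is.null(region_map) || is.null(default_target)))
    stop("regional_split rules need region_map and default_target")
  structure(list(kind = kind, source_codes = source_codes,
                 target_code = target_code, region_map = region_map,
                 default_target = default_target),
            class = "recoding_rule")
}

#' Apply species recoding rules to a tree record table
#'
#' @param records tree record table with `plot_id`, `species_code` and, for
#'   regional splits, `region_code`.
#' @param rules list of [recoding_rule()] objects. Rules must not conflict: no
#'   species code may be a source of two rules, and no rule's target may be
#'   another rule's source (which would make the result order-dependent).
#' @return The recoded table; rows matching `drop` rules are removed.
#' @export
apply_recoding <- function(records, rules) {
  if (length(rules) == 0L) return(records)
  stopifnot(all(vapply(rules, inherits, TRUE, "recoding_rule")))
  sources <- unlist(lapply(rules, `[[`, "source_codes"))
  if (anyDuplicated(sources))
    stop("conflicting rules: species code(s) ",
         paste(unique(sources[duplicated(sources)]), collapse = ", "),
         " targeted by more than one rule")
  targets <- unlist(lapply(rules, function(r)
    c(r$target_code, r$region_map, r$default_target)))
  bad <- intersect(targets, sources)
  if (length(bad))
    stop("conflicting rules: target code(s) ", paste(bad, collapse = ", "),
         " are also rule sources")

  for (r in rules) {
    hit <- records$species_code %in% r$source_codes
    if (!any(hit)) next
    if (r$kind == "drop") {
      records <- records[!hit, , drop = FALSE]
    } else if (r$kind == "merge") {
      records$species_code[hit] <- r$target_code
    } else { # regional_split
      if (is.null(records$region_code))
        stop("regional_split rule requires a region_code column")
      tgt <- r$region_map[records$region_code[hit]]
      tgt[is.na(tgt)] <- r$default_target
      records$species_code[hit] <- unname(tgt)
    }
  }
  rownames(records) <- NULL
  records
}

#' Drop plots carrying excluded flags
#'
#' Inventory plots flagged e.g. `nonstocked` (few or no trees) or as nonnative
#' forest types are removed before clustering. `plot_flags` is a
#' comma-separated flag string per record; a plot is excluded when any of its
#' records carries any excluded flag.
#'
#' @param records tree record table (column `plot_flags` optional).
#' @param exclude_flags character vector of flags that disqualify a plot.
#' @return The filtered table; warns (does not error) when nothing survives.
#' @export
filter_plots <- function(records, exclude_flags = c("nonstocked", "nonnative_type")) {
  if (is.null(records$plot_flags) || length(exclude_flags) == 0L)
    return(records)
  flags <- strsplit(as.character(records$plot_flags), ",", fixed = TRUE)
  hit <- vapply(flags, function(f) any(trimws(f) %in% exclude_flags), TRUE)
  bad_plots <- unique(records$plot_id[hit])
  out <- records[!(records$plot_id %in% bad_plots), , drop = FALSE]
  if (nrow(out) == 0L) warning("all plots excluded by flags")
  rownames(out) <- NULL
  out
}

#' Remove species occurring in too few plots
#'
#' Rare species skew dissimilarity-based clustering toward themselves, so
#' species found in fewer than `min_plots` distinct plots are removed. The
#' filter is applied once, not iterated; plots left with no records disappear
#' from the downstream importance-value matrix.
#'
#' @param records tree record table.
#' @param min_plots minimum number of distinct plots a species must occur in
#'   (default 250, appropriate for national-scale inventories of ~10^5 plots;
#'   scale it down for smaller data sets).
#' @return The filtered table.
#' @export
filter_rare_species <- function(records, min_plots = 250L) {
  if (min_plots < 1L) stop("min_plots must be >= 1")
  occ <- rowsum(rep(1L, nrow(records)),
                paste(records$species_code, records$plot_id, sep = "\r"))
  sp <- sub("\r.*$", "", rownames(occ))
  n_plots_of <- table(sp)
  keep_sp <- names(n_plots_of)[n_plots_of >= min_plots]
  out <- records[records$species_code %in% keep_sp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plots x species importance-value matrix
#'
#' The importance value of species `s` in plot `p` is the average of the
#' species' relative basal area and its relative stem abundance in the plot,
#' multiplied by 100:
#' `IV = 100 * (BA_s / sum(BA) + N_s / sum(N)) / 2`,
#' so each plot's row sums to 100. Missing per-stem basal areas are filled from
#' `dbh_cm` via [basal_area_from_dbh()]. Rows and columns are ordered
#' lexicographically for reproducibility.
#'
#' @param records tree record table; every retained plot must have at least one
#'   record with positive basal area.
#' @return Numeric matrix with `plot_id` rownames and species colnames; rows
#'   sum to 100.
#' @export
compute_iv <- function(records) {
  if (nrow(records) == 0L) stop("no records to compute importance values from")
  ba <- records$basal_area_m2
  if (is.null(ba)) ba <- rep(NA_real_, nrow(records))
  need <- is.na(ba)
  if (any(need)) {
    if (is.null(records$dbh_cm) || anyNA(records$dbh_cm[need]))
      stop("records need basal_area_m2 or dbh_cm")
    ba[need] <- basal_area_from_dbh(records$dbh_cm[need])
  }
  if (any(!is.finite(ba)) || any(ba <= 0))
    stop("all basal areas must be finite and strictly positive")

  plots <- sort(unique(as.character(records$plot_id)))
  sp <- sort(unique(as.character(records$species_code)))
  pi_ <- match(records$plot_id, plots)
  si <- match(records$species_code, sp)

  ba_m <- matrix(0, length(plots), length(sp), dimnames = list(plots, sp))
  n_m <- ba_m
  cell <- (si - 1L) * length(plots) + pi_
  ba_acc <- rowsum(ba, cell)
  n_acc <- rowsum(rep(1, length(cell)), cell)
  pos <- as.integer(rownames(ba_acc))
  ba_m[pos] <- ba_acc
  n_m[pos] <- n_acc
  tot_ba <- rowSums(ba_m)
  if (any(tot_ba <= 0)) stop("plot with zero total basal area")
  iv <- 100 * (ba_m / tot_ba + n_m / rowSums(n_m)) / 2
  iv <- iv[, colSums(iv) > 0, drop = FALSE]
  iv
}

#' Read / write tree record and importance-value tables
#'
#' Plain tab-separated text with a header row; the on-disk interchange format
#' for every pipeline stage.
#'
#' @param path file path.
#' @param records,ivm object to write.
#' @name assemblr_io
#' @export
read_records <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(plot_id = "character",
                                   species_code = "character"))
}

#' @rdname assemblr_io
#' @export
write_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname assemblr_io
#' @export
write_iv_matrix <- function(ivm, path) {
  df <- data.frame(plot_id = rownames(ivm), ivm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname assemblr_io
#' @export
read_iv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$plot_id
  m
}
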