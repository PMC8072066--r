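# Preprocessing of per-mouse observation tables: loading/validation,
# time-zero adjustment, observation-window restriction, per-mouse
# normalization to the HSC gate, time-point pooling and pooled-variance
# standard errors.

OBS_REQUIRED <- c("mouse_id", "dataset", "time_days", "compartment",
                  "frequency")
OBS_COMPARTMENTS <- c("HSC", "ST-HSC", "MPP")

validate_observations <- function(tab) {
  missing <- setdiff(OBS_REQUIRED, names(tab))
  if (length(missing) > 0)
    stop("missing required columns: ", paste(missing, collapse = ", "))
  if (nrow(tab) == 0) stop("observation table is empty")
  if (!("count" %in% names(tab))) tab$count <- NA_real_
  tab$time_days <- as.numeric(tab$time_days)
  tab$frequency <- as.numeric(tab$frequency)
  tab$count <- as.numeric(tab$count)
  if (anyNA(tab$time_days) || any(tab$time_days < 0))
    stop("`time_days` must be non-negative numbers")
  bad <- which(is.na(tab$frequency) | tab$frequency < 0 | tab$frequency > 1)
  if (length(bad) > 0)
    stop("frequency outside [0, 1] in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  badc <- which(!is.na(tab$count) & tab$count < 0)
  if (length(badc) > 0)
    stop("negative count in row(s): ",
         paste(utils::head(badc, 10), collapse = ", "))
  key <- paste(tab$mouse_id, tab$dataset, tab$time_days, tab$compartment)
  if (anyDuplicated(key))
    stop("duplicate (mouse, dataset, time, compartment) row(s): ",
         paste(utils::head(which(duplicated(key)), 10), collapse = ", "))
  class(tab) <- c("hsc_observations", "data.frame")
  tab
}

#' Load a per-mouse observation table
#'
#' Reads delimited text (comma- or tab-separated, chosen by file
#' extension unless `sep` is given) with one row per mouse, time point and
#' compartment. Required columns: `mouse_id`, `dataset`, `time_days`,
#' `compartment`, `frequency`; optional `count`. Column names can be
#' remapped via `col_map`. Frequencies outside `[0, 1]`, negative counts
#' and duplicate rows are rejected with row-level error messages.
#'
#' @param path Input file path.
#' @param col_map Optional named character vector mapping required names to
#'   the names used in the file, e.g. `c(time_days = "day")`.
#' @param sep Field separator; default `","` for `.csv`, otherwise tab.
#' @return A validated `data.frame` of class `hsc_observations`.
#' @export
load_observations <- function(path, col_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      j <- match(col_map[[std]], names(tab))
      if (is.na(j)) stop("mapped column not found: ", col_map[[std]])
      names(tab)[j] <- std
    }
  }
  validate_observations(tab)
}

#' Write an observation table as delimited text
#'
#' @param table An `hsc_observations` data frame.
#' @param path Output path (`.csv` for comma-separated, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_observations <- function(table, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(table, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Shift the time axis to the effective induction time
#'
#' Tamoxifen-induced labeling takes effect with a short delay, so the
#' nominal measurement times are shifted back by `offset_days` (default 2
#' days; designs with sparse early sampling may use 1 day). Rows whose
#' shifted time would be negative are dropped with a warning.
#'
#' @param table An `hsc_observations` data frame.
#' @param offset_days A single offset, or a named vector of per-dataset
#'   offsets (days).
#' @return The adjusted table; attribute `dropped` holds the number of
#'   dropped rows.
#' @export
adjust_time_zero <- function(table, offset_days = 2) {
  off <- if (length(offset_days) == 1L && is.null(names(offset_days))) {
    rep(as.numeric(offset_days), nrow(table))
  } else {
    o <- offset_days[table$dataset]
    if (anyNA(o)) stop("no offset given for dataset(s): ",
                       paste(unique(table$dataset[is.na(o)]), collapse = ", "))
    as.numeric(o)
  }
  table$time_days <- table$time_days - off
  neg <- table$time_days < 0
  if (any(neg))
    warning(sum(neg), " row(s) before the effective induction time dropped")
  out <- table[!neg, , drop = FALSE]
  attr(out, "dropped") <- sum(neg)
  out
}

#' Restrict the observation window
#'
#' Keeps rows with `time_days <= max_days` (inclusive). The default window
#' of 40 weeks (280 days) excludes aging-related changes in compartment
#' sizes and rates, which the constant-rate model does not describe.
#'
#' @param table An `hsc_observations` data frame.
#' @param max_days Window length in days; must be positive.
#' @return The restricted table; attribute `dropped` holds the number of
#'   removed rows.
#' @export
restrict_window <- function(table, max_days = 280) {
  if (!is.numeric(max_days) || max_days <= 0)
    stop("`max_days` must be positive")
  keep <- table$time_days <= max_days
  out <- table[keep, , drop = FALSE]
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Normalize each mouse's downstream frequencies to its HSC frequency
#'
#' Adds a `frequency_norm` column: for ST-HSC and MPP rows the labeled
#' frequency divided by the same mouse's HSC labeled frequency (`NA` for
#' HSC rows). Mice with a zero or missing HSC frequency get `NA` with a
#' warning.
#'
#' @param table An `hsc_observations` data frame.
#' @return The table with a `frequency_norm` column.
#' @export
normalize_observations <- function(table) {
  key <- paste(table$mouse_id, table$dataset, sep = "\r")
  hsc <- table$compartment == "HSC"
  f_hsc <- setNames(table$frequency[hsc], key[hsc])[key]
  bad <- is.na(f_hsc) | f_hsc == 0
  if (any(bad & !hsc))
    warning(length(unique(key[bad])),
            " mouse/mice with zero or missing HSC frequency; ",
            "normalized values masked")
  table$frequency_norm <- ifelse(hsc | bad, NA_real_,
                                 table$frequency / f_hsc)
  table
}

#' Pooling bins used for the dense early time course
#'
#' Eight non-overlapping day intervals used to pool a densely but
#' irregularly sampled cohort to as many effective time points as the
#' sparser comparison cohort: 0-20, 27-50, 55-69, 78-95, 104-129, 130-153,
#' 160-179 and 188-208 days.
#'
#' @return A `data.frame` with columns `lo` and `hi` (days, inclusive).
#' @export
tie2_bins <- function() {
  data.frame(lo = c(0, 27, 55, 78, 104, 130, 160, 188),
             hi = c(20, 50, 69, 95, 129, 153, 179, 208))
}

#' Pool observations into time bins
#'
#' Averages per-mouse observations within time bins, separately per
#' dataset and compartment. With `bins = NULL` every distinct observation
#' time forms its own bin. The representative bin time is the mean of the
#' member observation times (a bin-midpoint alternative is available).
#' Rows outside all bins are dropped with a warning. Within-bin variances
#' and stream sample sizes are retained for [add_pooled_sem()].
#'
#' @param table An `hsc_observations` data frame (normally after
#'   [normalize_observations()]).
#' @param bins A `data.frame` with columns `lo`, `hi` (inclusive day
#'   intervals), e.g. [tie2_bins()], or `NULL` for one bin per distinct
#'   time.
#' @param bin_time `"mean"` (mean member time, default) or `"midpoint"`.
#' @return A `data.frame` of class `hsc_pooled`: one row per (dataset,
#'   compartment, bin) with means, within-bin variances and counts for
#'   the raw frequency, normalized frequency and count streams.
#' @export
pool_timepoints <- function(table, bins = NULL, bin_time = c("mean", "midpoint")) {
  bin_time <- match.arg(bin_time)
  if (is.null(bins)) {
    ut <- sort(unique(table$time_days))
    bins <- data.frame(lo = ut, hi = ut)
  }
  if (!all(c("lo", "hi") %in% names(bins)) || any(bins$hi < bins$lo))
    stop("`bins` must have lo <= hi columns")
  bins <- bins[order(bins$lo), , drop = FALSE]
  if (nrow(bins) > 1 && any(bins$lo[-1] <= bins$hi[-nrow(bins)]))
    stop("bins overlap")
  if (!("frequency_norm" %in% names(table)))
    table$frequency_norm <- NA_real_

  ib <- rep(NA_integer_, nrow(table))
  for (b in seq_len(nrow(bins)))
    ib[table$time_days >= bins$lo[b] & table$time_days <= bins$hi[b]] <- b
  if (anyNA(ib))
    warning(sum(is.na(ib)), " row(s) outside all bins dropped")
  keep <- !is.na(ib)
  tab <- table[keep, , drop = FALSE]
  ib <- ib[keep]

  grp <- interaction(tab$dataset, tab$compartment, ib, drop = TRUE)
  stat <- function(x, fun) as.numeric(tapply(x, grp, fun))
  nn <- function(x) as.numeric(tapply(x, grp, function(v) sum(!is.na(v))))
  mfun <- function(x) mean(x, na.rm = TRUE)
  vfun <- function(x) if (sum(!is.na(x)) >= 2) var(x, na.rm = TRUE) else NA_real_
  first <- function(x) as.character(tapply(as.character(x), grp, `[`, 1))

  out <- data.frame(
    dataset = first(tab$dataset),
    compartment = first(tab$compartment),
    bin = as.integer(as.numeric(tapply(ib, grp, `[`, 1))),
    stringsAsFactors = FALSE)
  out$bin_lo <- bins$lo[out$bin]
  out$bin_hi <- bins$hi[out$bin]
  out$time <- if (bin_time == "mean") stat(tab$time_days, mfun)
              else (out$bin_lo + out$bin_hi) / 2
  out$n_mice <- as.integer(as.numeric(tapply(grp, grp, length)))
  for (q in c("frequency", "frequency_norm", "count")) {
    out[[paste0("mean_", q)]] <- stat(tab[[q]], mfun)
    out[[paste0("var_", q)]] <- stat(tab[[q]], vfun)
    out[[paste0("n_", q)]] <- nn(tab[[q]])
  }
  out <- out[order(out$dataset, out$compartment, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bins") <- bins
  attr(out, "dropped") <- sum(!keep)
  class(out) <- c("hsc_pooled", "data.frame")
  out
}

#' Pooled-variance standard errors of binned means
#'
#' A single measurement variance is estimated per observable stream
#' (compartment x quantity) by pooling within-bin variances across bins --
#' and, with `joint = TRUE`, across datasets:
#' \deqn{s^2_{pool} = \sum_g (n_g - 1) s_g^2 / \sum_g (n_g - 1),}
#' so that bins with few mice get honestly wide standard errors
#' \eqn{SEM_b = \sqrt{s^2_{pool} / n_b}}. Streams whose groups are all
#' singletons cannot be pooled and trigger an error asking for an explicit
#' variance.
#'
#' @param pooled An `hsc_pooled` table or a list of them (one per dataset).
#' @param joint Pool variances across all supplied datasets (default) or
#'   separately per dataset.
#' @return The input with `sem_frequency`, `sem_frequency_norm` and
#'   `sem_count` columns added; attribute `pooled_variance` holds the
#'   per-stream pooled variances.
#' @export
add_pooled_sem <- function(pooled, joint = TRUE) {
  single <- is.data.frame(pooled)
  plist <- if (single) list(pooled) else pooled
  all_tab <- do.call(rbind, lapply(plist, as.data.frame))
  quantities <- c("frequency", "frequency_norm", "count")

  pool_var <- function(tab, q) {
    v <- tab[[paste0("var_", q)]]
    n <- tab[[paste0("n_", q)]]
    ok <- !is.na(v) & n >= 2
    if (!any(ok)) return(NA_real_)
    sum((n[ok] - 1) * v[ok]) / sum(n[ok] - 1)
  }

  pv_table <- NULL
  result <- lapply(seq_along(plist), function(i) {
    tab <- plist[[i]]
    for (q in quantities) {
      sem <- rep(NA_real_, nrow(tab))
      for (cmp in unique(tab$compartment)) {
        sel_all <- if (joint) all_tab$compartment == cmp
                   else all_tab$compartment == cmp &
                        all_tab$dataset %in% unique(tab$dataset)
        measured <- sum(all_tab[[paste0("n_", q)]][sel_all]) > 0
        if (!measured) next
        pv <- pool_var(all_tab[sel_all, , drop = FALSE], q)
        if (is.na(pv))
          stop("all groups are singletons for stream (", cmp, ", ", q,
               "); pooled variance undefined -- supply explicit variances")
        sel <- tab$compartment == cmp
        nb <- tab[[paste0("n_", q)]][sel]
        sem[sel] <- ifelse(nb > 0, sqrt(pv / nb), NA_real_)
        pv_table <<- rbind(pv_table,
                           data.frame(compartment = cmp, quantity = q,
                                      dataset = if (joint) "(joint)"
                                                else unique(tab$dataset)[1],
                                      pooled_variance = pv))
      }
      tab[[paste0("sem_", q)]] <- sem
    }
    attr(tab, "pooled_variance") <- unique(pv_table)
    tab
  })
  if (single) result[[1]] else setNames(result, names(plist))
}

#' Write a pooled dataset as delimited text
#'
#' @param pooled An `hsc_pooled` data frame.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_pooled <- function(pooled, path) {
  utils::write.table(as.data.frame(pooled), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
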