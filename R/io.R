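#' Count table of samples by taxa
#'
#' Validated container for a `K x D` matrix of non-negative integer sequence
#' counts with per-sample depths `n_k` equal to row sums.
#'
#' @param counts numeric matrix of counts; rows are samples, columns taxa.
#' @param taxa_names,sample_ids optional labels overriding dimnames.
#' @return object of class `count_table` with fields `counts`, `depths`,
#'   `taxa_names`, `sample_ids`.
#' @export
count_table <- function(counts, taxa_names = colnames(counts),
                        sample_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(taxa_names)) taxa_names <- paste0("t", seq_len(ncol(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(counts)))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("count table entry at sample '", sample_ids[bad[1L, 1L]],
         "', taxon '", taxa_names[bad[1L, 2L]],
         "' is not a non-negative integer", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in count table", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(sample_ids, taxa_names)
  structure(list(counts = counts, depths = rowSums(counts),
                 taxa_names = taxa_names, sample_ids = sample_ids),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "samples x", ncol(x$counts),
      "taxa; median depth", stats::median(x$depths), "\n")
  invisible(x)
}

#' Read and write count tables
#'
#' TSV layout: one row per sample, first column `sample_id`, remaining
#' columns one per taxon.  BIOM files are handled through the `biomformat`
#' package (taxa are BIOM observations, samples are BIOM samples).
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @return a [count_table] (readers) or `path`, invisibly (writers).
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(df)) {
      stop("count TSV must have a sample_id column", call. = FALSE)
    }
    m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
    rownames(m) <- df$sample_id
    count_table(m)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("the biomformat package is required for BIOM input", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")   # taxa x samples
    count_table(t(m))
  }
}

#' @rdname read_count_table
#' @param table a [count_table].
#' @export
write_count_table <- function(table, path, format = c("tsv", "biom")) {
  stopifnot(inherits(table, "count_table"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(sample_id = table$sample_ids,
                     table$counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("the biomformat package is required for BIOM output", call. = FALSE)
    }
    b <- biomformat::make_biom(t(table$counts))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

# exact rational fraction helper: counts retained / total as reduced integers
.exact_fraction <- function(num, den) {
  g <- function(a, b) if (b == 0) a else Recall(b, a %% b)
  d <- g(num, den)
  if (d == 0) d <- 1
  list(numerator = num / d, denominator = den / d,
       value = if (den > 0) num / den else NA_real_)
}

#' Filter samples by sequencing depth
#'
#' Retains samples whose depth is strictly greater than `min_depth`
#' (the "more than" reading: a sample at exactly the threshold is removed).
#'
#' @param table a [count_table].
#' @param min_depth non-negative depth threshold (default 5000).
#' @return list with `table` (filtered [count_table]) and `report`
#'   (removed ids and the exact retained fraction of total counts).
#' @export
filter_samples <- function(table, min_depth = 5000) {
  stopifnot(inherits(table, "count_table"), min_depth >= 0)
  keep <- table$depths > min_depth
  filtered <- count_table(table$counts[keep, , drop = FALSE],
                          table$taxa_names, table$sample_ids[keep])
  report <- list(
    removed_ids = table$sample_ids[!keep],
    n_removed = sum(!keep),
    retained_count_fraction = .exact_fraction(sum(table$counts[keep, ]),
                                              sum(table$counts)))
  list(table = filtered, report = report)
}

#' Filter taxa by count prevalence
#'
#' Retains taxa present with at least `min_count` counts in strictly more
#' than a `min_prevalence` fraction of samples (defaults: at least 3 counts
#' in more than 90% of samples).  The prevalence comparison is done in exact
#' rational arithmetic so threshold boundaries are unambiguous.
#'
#' @param table a [count_table].
#' @param min_count minimum per-sample count for presence.
#' @param min_prevalence required fraction of samples, in `[0, 1]`.
#' @return list with `table` and `report` (removed taxa, exact retained
#'   count fraction).
#' @export
filter_taxa <- function(table, min_count = 3, min_prevalence = 0.9) {
  stopifnot(inherits(table, "count_table"),
            min_count >= 0, min_prevalence >= 0, min_prevalence <= 1)
  K <- nrow(table$counts)
  hits <- colSums(table$counts >= min_count)
  # rationalize min_prevalence to num/den so n_hits/K > num/den is exact
  den <- 1e6
  num <- round(min_prevalence * den)
  keep <- hits * den > num * K
  filtered <- count_table(table$counts[, keep, drop = FALSE],
                          table$taxa_names[keep], table$sample_ids)
  report <- list(
    removed_taxa = table$taxa_names[!keep],
    n_removed = sum(!keep),
    retained_count_fraction = .exact_fraction(sum(table$counts[, keep]),
                                              sum(table$counts)))
  list(table = filtered, report = report)
}

#' Aggregate taxa to a higher rank
#'
#' Sums counts within groups given a pre-computed mapping (e.g. sequence
#' variant to family).  Classification itself is out of scope; the mapping
#' comes from upstream tools.
#'
#' @param table a [count_table].
#' @param mapping data frame with columns `taxon` and `group` (or a named
#'   character vector `taxon -> group`).
#' @return aggregated [count_table] with one column per group.
#' @export
aggregate_taxa <- function(table, mapping) {
  stopifnot(inherits(table, "count_table"))
  if (is.data.frame(mapping)) {
    map <- stats::setNames(as.character(mapping$group),
                           as.character(mapping$taxon))
  } else {
    map <- mapping
  }
  if (!all(table$taxa_names %in% names(map))) {
    stop("mapping is missing taxa: ",
         paste(utils::head(setdiff(table$taxa_names, names(map)), 5L),
               collapse = ", "), call. = FALSE)
  }
  groups <- map[table$taxa_names]
  agg <- t(rowsum(t(table$counts), groups))
  count_table(agg, colnames(agg), table$sample_ids)
}

#' Read a sample manifest into a schedule
#'
#' The manifest TSV has columns `sample_id`, `vessel`, `time` with time
#' indices on the declared base interval; duplicate (vessel, time) pairs are
#' technical replicates.  Gaps in the time grid become marginalized steps.
#'
#' @param path manifest TSV path.
#' @param counts optional [count_table] to validate sample ids against.
#' @return a [sample_schedule].
#' @export
read_manifest <- function(path, counts = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "vessel", "time")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns sample_id, vessel, time", call. = FALSE)
  }
  if (nrow(df) == 0L) stop("manifest is empty", call. = FALSE)
  if (!is.null(counts)) {
    missing_ids <- setdiff(df$sample_id, counts$sample_ids)
    if (length(missing_ids) > 0L) {
      stop("manifest sample ids absent from count table: ",
           paste(utils::head(missing_ids, 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  sample_schedule(df$sample_id, df$vessel, df$time)
}

#' @rdname read_manifest
#' @param schedule a [sample_schedule] to write.
#' @export
write_manifest <- function(schedule, path) {
  st <- schedule$steps[schedule$steps$observed, ]
  utils::write.table(
    data.frame(sample_id = st$sample_id, vessel = st$vessel, time = st$time),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML (or JSON) with top-level keys `paths`, `priors`, `fit`, `analysis`,
#' `seed`; unknown keys anywhere at the top level or inside `priors`/`fit`
#' are rejected to catch typos.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("paths", "priors", "fit", "analysis", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$priors)) {
    bad <- setdiff(names(cfg$priors), names(formals(mallard_priors)))
    if (length(bad) > 0L) {
      stop("unknown prior fields: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(cfg$fit)) {
    bad <- setdiff(names(cfg$fit), names(formals(fit_config)))
    if (length(bad) > 0L) {
      stop("unknown fit fields: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(cfg$paths)) {
    for (p in unlist(cfg$paths)) {
      if (!file.exists(p)) stop("config path does not exist: ", p,
                                call. = FALSE)
    }
  }
  cfg
}

# hash an R object for provenance logging (serialized to a tempfile)
.config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

#' Structured log line
#'
#' Writes a timestamped message recording the seed and a hash of the
#' configuration that produced an output.
#'
#' @param event short event name.
#' @param seed integer seed in effect.
#' @param config configuration object (hashed, not printed).
#' @param ... further `name = value` fields appended to the line.
#' @export
mallard_log <- function(event, seed = NA, config = NULL, ...) {
  extra <- list(...)
  fields <- c(sprintf("time=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
              sprintf("event=%s", event),
              sprintf("seed=%s", seed),
              if (!is.null(config)) sprintf("config_hash=%s",
                                            .config_hash(config)),
              vapply(seq_along(extra), function(i)
                sprintf("%s=%s", names(extra)[i], extra[[i]]), character(1)))
  message(paste(fields, collapse = " "))
  invisible(NULL)
}
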