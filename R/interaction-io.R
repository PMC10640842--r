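#' @keywords internal
"_PACKAGE"

TREATMENT_LEVELS <- c("C", "F", "H", "HF")

#' Read and validate long-format interaction records
#'
#' Ingests a CSV of plant-insect visitation records (one row per plot x plant
#' x insect, with a visit count) and returns a validated, season-aggregated
#' interaction table. Duplicate (plot, plant, insect) rows -- e.g. repeated
#' sampling events within a season -- are summed; zero-count rows are dropped
#' with a warning.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Named character vector mapping the canonical column names
#'   `plot`, `block`, `treatment`, `plant`, `insect`, `count` to the column
#'   names used in the file. Defaults to the identity mapping.
#' @return A data frame of class `interaction_table` with columns
#'   `plot`, `block`, `treatment`, `plant`, `insect`, `count`, unique in
#'   (plot, plant, insect).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(plot = "p1", block = "b1", treatment = "C",
#'                      plant = "A", insect = "x", count = 2L), tf,
#'           row.names = FALSE)
#' read_interactions(tf)
#' @export
read_interactions <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop("interaction file not found: ", path)
  }
  canonical <- c("plot", "block", "treatment", "plant", "insect", "count")
  if (is.null(schema)) {
    schema <- stats::setNames(canonical, canonical)
  }
  missing_map <- setdiff(canonical, names(schema))
  if (length(missing_map) > 0) {
    stop("schema is missing a mapping for column(s): ",
         paste(missing_map, collapse = ", "))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(schema[canonical]), names(raw))
  if (length(missing_cols) > 0) {
    stop("input file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) warning("no interaction records in ", path)
  df <- data.frame(
    plot      = as.character(raw[[schema[["plot"]]]]),
    block     = as.character(raw[[schema[["block"]]]]),
    treatment = as.character(raw[[schema[["treatment"]]]]),
    plant     = as.character(raw[[schema[["plant"]]]]),
    insect    = as.character(raw[[schema[["insect"]]]]),
    count     = raw[[schema[["count"]]]],
    stringsAsFactors = FALSE
  )
  as_interaction_table(df)
}

#' Coerce and validate an interaction table
#'
#' @param df Data frame with columns `plot`, `block`, `treatment`, `plant`,
#'   `insect`, `count`.
#' @return A validated `interaction_table` (duplicates summed, zero counts
#'   dropped with a warning).
#' @export
as_interaction_table <- function(df) {
  required <- c("plot", "block", "treatment", "plant", "insect", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  if (nrow(df) > 0) {
    cnt <- df$count
    bad <- which(is.na(cnt) | !is.finite(as.numeric(cnt)) |
                   as.numeric(cnt) != round(as.numeric(cnt)) |
                   as.numeric(cnt) < 0)
    if (length(bad) > 0) {
      stop("non-integer or negative count at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    df$count <- as.integer(round(as.numeric(cnt)))
    zeros <- df$count == 0
    if (any(zeros)) {
      warning(sum(zeros), " zero-count row(s) dropped")
      df <- df[!zeros, , drop = FALSE]
    }
    bad_trt <- !df$treatment %in% TREATMENT_LEVELS
    if (any(bad_trt)) {
      stop("unknown treatment code(s): ",
           paste(unique(df$treatment[bad_trt]), collapse = ", "))
    }
    # a plot belongs to exactly one block and one treatment
    pb <- unique(df[c("plot", "block", "treatment")])
    if (anyDuplicated(pb$plot)) {
      stop("plot(s) mapped to more than one block/treatment: ",
           paste(unique(pb$plot[duplicated(pb$plot)]), collapse = ", "))
    }
    # season aggregation: sum duplicates over sampling events
    key <- paste(df$plot, df$plant, df$insect, sep = "\r")
    if (anyDuplicated(key)) {
      agg <- stats::aggregate(count ~ plot + block + treatment + plant + insect,
                              data = df, FUN = sum)
      df <- agg[required]
    }
    df <- df[order(df$plot, df$plant, df$insect), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Read per-plot metadata
#'
#' @param path CSV with columns `plot`, `block`, `treatment`,
#'   `plants_bloomed`, and either `display` directly or `inflorescences` and
#'   `inflorescence_area` (display = inflorescence count x mean area, mm^2).
#' @param n_plants Number of planted species (upper bound for
#'   `plants_bloomed`); default 7.
#' @return Data frame with columns `plot`, `block`, `treatment`,
#'   `plants_bloomed`, `display`, `display_log`.
#' @export
read_metadata <- function(path, n_plants = 7L) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_plot_metadata(raw, n_plants = n_plants)
}

#' Validate per-plot metadata
#' @param df Data frame; see [read_metadata()] for the accepted columns.
#' @param n_plants Planted species count bound; default 7.
#' @export
as_plot_metadata <- function(df, n_plants = 7L) {
  required <- c("plot", "block", "treatment", "plants_bloomed")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"display" %in% names(df)) {
    if (!all(c("inflorescences", "inflorescence_area") %in% names(df))) {
      stop("metadata needs either `display` or both `inflorescences` ",
           "and `inflorescence_area`")
    }
    df$display <- df$inflorescences * df$inflorescence_area
  }
  if (any(df$plants_bloomed < 0 | df$plants_bloomed > n_plants)) {
    stop("plants_bloomed outside [0, ", n_plants, "]")
  }
  if (any(!df$treatment %in% TREATMENT_LEVELS)) {
    stop("unknown treatment code in metadata")
  }
  if (anyDuplicated(df$plot)) stop("duplicated plot in metadata")
  out <- data.frame(
    plot = as.character(df$plot),
    block = as.character(df$block),
    treatment = as.character(df$treatment),
    plants_bloomed = as.integer(df$plants_bloomed),
    display = as.numeric(df$display),
    stringsAsFactors = FALSE
  )
  out$display_log <- ifelse(out$display > 0, log(out$display), NA_real_)
  out
}

#' Build one plot's weighted bipartite network
#'
#' Restricts the plant x insect visit matrix to species with at least one
#' visit in the plot; rows and columns are sorted by label so that the same
#' records always yield the same matrix regardless of input order.
#'
#' @param table An `interaction_table`.
#' @param plot_id Plot identifier.
#' @param meta One-row metadata data frame for the plot (see
#'   [as_plot_metadata()]); optional, carried along for downstream metrics.
#' @return A `plot_network`: list with `matrix` (integer plants x insects),
#'   `plot_id`, and `meta`.
#' @export
build_plot_network <- function(table, plot_id, meta = NULL) {
  rec <- table[table$plot == plot_id, , drop = FALSE]
  if (nrow(rec) == 0) {
    stop("empty network: plot '", plot_id, "' has no interaction records")
  }
  plants <- sort(unique(rec$plant))
  insects <- sort(unique(rec$insect))
  A <- matrix(0L, length(plants), length(insects),
              dimnames = list(plants, insects))
  A[cbind(match(rec$plant, plants), match(rec$insect, insects))] <-
    as.integer(rec$count)
  if (!is.null(meta)) {
    meta <- meta[meta$plot == plot_id, , drop = FALSE]
    if (nrow(meta) != 1) stop("metadata must have exactly one row for plot '",
                              plot_id, "'")
  }
  structure(list(matrix = A, plot_id = plot_id, meta = meta),
            class = "plot_network")
}

#' @export
print.plot_network <- function(x, ...) {
  cat("plot_network '", x$plot_id, "': ", nrow(x$matrix), " plants x ",
      ncol(x$matrix), " insects, total weight ", sum(x$matrix), "\n", sep = "")
  invisible(x)
}

#' Build all non-empty plot networks
#'
#' @param table An `interaction_table`.
#' @param meta Optional metadata data frame covering the plots. Plots present
#'   in `meta` but without records (e.g. a plot that received no visitors)
#'   are skipped with a message, mirroring exclusion of empty networks.
#' @return Named list of `plot_network` objects.
#' @export
build_all_networks <- function(table, meta = NULL) {
  plots <- sort(unique(table$plot))
  if (!is.null(meta)) {
    empty <- setdiff(meta$plot, plots)
    if (length(empty) > 0) {
      message("plot(s) with no visits excluded: ", paste(empty, collapse = ", "))
    }
  }
  nets <- lapply(plots, function(p) build_plot_network(table, p, meta))
  stats::setNames(nets, plots)
}

#' Pool interaction records across all plots of one treatment
#'
#' @param table An `interaction_table`.
#' @param treatment One of `"C"`, `"F"`, `"H"`, `"HF"`.
#' @return A `plot_network` whose counts are summed over the treatment's
#'   plots; `plot_id` is the treatment code.
#' @export
pool_by_treatment <- function(table, treatment) {
  if (!treatment %in% TREATMENT_LEVELS) {
    stop("unknown treatment code: ", treatment)
  }
  rec <- table[table$treatment == treatment, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records for treatment ", treatment)
  agg <- stats::aggregate(count ~ plant + insect, data = rec, FUN = sum)
  plants <- sort(unique(agg$plant))
  insects <- sort(unique(agg$insect))
  A <- matrix(0L, length(plants), length(insects),
              dimnames = list(plants, insects))
  A[cbind(match(agg$plant, plants), match(agg$insect, insects))] <-
    as.integer(agg$count)
  structure(list(matrix = A, plot_id = treatment, meta = NULL),
            class = "plot_network")
}

#' Write a per-network metrics table to CSV
#'
#' Lossless round-trip: [read_metrics_table()] on the written file returns
#' the same values.
#'
#' @param rows Data frame of per-network metrics (one row per network), as
#'   produced by [compute_all()] over plots.
#' @param path Output file path.
#' @export
write_metrics_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Plot-level abundance and richness summary
#'
#' Fast per-plot totals (no network metrics): visitor abundance, realized
#' insect richness, joined to the plot metadata. Plots without visits are
#' dropped, mirroring the exclusion of empty networks.
#'
#' @param table An `interaction_table`.
#' @param metadata Plot metadata (see [as_plot_metadata()]).
#' @return Data frame: metadata columns plus `abundance` and
#'   `insect_richness`.
#' @export
plot_level_summary <- function(table, metadata) {
  ab <- tapply(table$count, table$plot, sum)
  rich <- tapply(table$insect, table$plot, function(x) length(unique(x)))
  out <- metadata[metadata$plot %in% names(ab), , drop = FALSE]
  out$abundance <- as.numeric(ab[out$plot])
  out$insect_richness <- as.numeric(rich[out$plot])
  rownames(out) <- NULL
  out
}
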