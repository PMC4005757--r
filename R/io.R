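# Domain containers and readers for uniparental genotype tables.
#
# A genotype table is a plain data.frame (one row per sampled individual)
# carrying `individual_id`, `population_id`, optional haplogroup calls
# (`y_haplogroup`, `mt_haplogroup`), integer Y-STR repeat columns (DYS*),
# and an `hvs_variants` column holding rCRS-relative control-region variant
# tokens such as "16224C", separated by ";".  Missing values are written to
# file as the sentinel "." (never as an empty string).

MT_GENOME_LENGTH <- 16569L
# control-region window typed in the surveys this package targets
HVS_WINDOW_START <- 15975L
HVS_WINDOW_END <- 155L
# HVS-I proper, the stretch the rho clock is calibrated on
HVS1_REGION <- c(16024L, 16365L)

MISSING_TOKEN <- "."

#' Construct and validate a genotype table
#'
#' @param df data.frame with at least `individual_id` and `population_id`.
#' @param marker_system one of "Y", "MT", "BOTH".
#' @param str_loci character vector naming the STR columns to use in
#'   analyses; defaults to every `DYS*`/`GATA*` column except the
#'   unresolvable multi-copy pair DYS385a/b, which is never analysed.
#' @return the validated data.frame, classed `genotype_tbl`, with
#'   attributes `marker_system` and `str_loci`.
#' @export
genotype_table <- function(df, marker_system = c("Y", "MT", "BOTH"),
                           str_loci = NULL) {
  marker_system <- match.arg(marker_system)
  stopifnot(is.data.frame(df))
  for (col in c("individual_id", "population_id")) {
    if (!col %in% names(df)) {
      stop("schema error: required column '", col, "' is missing")
    }
  }
  candidates <- grep("^(DYS|GATA)", names(df), value = TRUE)
  banned <- grep("^DYS385", candidates, value = TRUE)
  if (length(banned) && is.null(str_loci)) {
    warning("excluding multi-copy loci from the analysis profile: ",
            paste(banned, collapse = ", "))
  }
  if (is.null(str_loci)) str_loci <- setdiff(candidates, banned)
  if (any(grepl("^DYS385", str_loci))) {
    stop("DYS385a/b cannot be part of an analysis STR profile")
  }
  for (locus in str_loci) {
    v <- df[[locus]]
    if (is.character(v)) {
      bad <- which(!is.na(v) & v != MISSING_TOKEN &
                     !grepl("^[0-9]+$", v))
      if (length(bad)) {
        stop("parse error: non-integer repeat count at locus ", locus,
             ", row ", bad[1])
      }
      v[v == MISSING_TOKEN] <- NA
      df[[locus]] <- as.integer(v)
    }
    bad <- which(!is.na(df[[locus]]) &
                   (df[[locus]] != round(df[[locus]]) | df[[locus]] <= 0))
    if (length(bad)) {
      stop("parse error: non-positive or non-integer repeat count at locus ",
           locus, ", row ", bad[1])
    }
    df[[locus]] <- as.integer(df[[locus]])
  }
  if ("hvs_variants" %in% names(df)) {
    sets <- parse_variant_tokens(df$hvs_variants)
    for (i in seq_along(sets)) {
      pos <- variant_positions(sets[[i]])
      out <- pos[!in_hvs_window(pos)]
      if (length(out)) {
        stop("variant position ", out[1], " (row ", i,
             ") lies outside the typed control-region window ",
             HVS_WINDOW_START, "-", HVS_WINDOW_END)
      }
    }
  }
  structure(df, class = c("genotype_tbl", class(df)),
            marker_system = marker_system, str_loci = str_loci)
}

#' STR loci used for analysis
#' @param x a genotype table.
#' @export
str_loci <- function(x) attr(x, "str_loci")

#' HVS variant sets, one character vector per individual
#' @param x a genotype table with an `hvs_variants` column.
#' @export
hvs_variant_sets <- function(x) {
  if (!"hvs_variants" %in% names(x)) {
    stop("no hvs_variants column in this table")
  }
  parse_variant_tokens(x$hvs_variants)
}

parse_variant_tokens <- function(strings) {
  lapply(strings, function(s) {
    if (is.na(s) || s == MISSING_TOKEN || !nzchar(s)) return(character(0))
    tok <- strsplit(s, ";", fixed = TRUE)[[1]]
    tok <- tok[nzchar(tok)]
    bad <- tok[!grepl("^[0-9]+[ACGTacgt-]$", tok)]
    if (length(bad)) stop("malformed variant token: ", bad[1])
    sort(unique(toupper(tok)))
  })
}

variant_positions <- function(tokens) {
  as.integer(sub("[ACGT-]$", "", tokens))
}

in_hvs_window <- function(pos) {
  (pos >= HVS_WINDOW_START & pos <= MT_GENOME_LENGTH) |
    (pos >= 1L & pos <= HVS_WINDOW_END)
}

#' Read a genotype table from delimited text
#'
#' Accepts comma- or tab-separated text with a header line; the separator is
#' sniffed from the header.  Repeat counts must be positive integers (or the
#' missing sentinel "."); the multi-copy loci DYS385a/b, if present, are
#' retained as raw columns but excluded from the analysis profile with a
#' warning.
#'
#' @param path file path.
#' @param marker_system one of "Y", "MT", "BOTH".
#' @return a `genotype_tbl` data.frame.
#' @export
read_genotype_table <- function(path, marker_system = c("Y", "MT", "BOTH")) {
  marker_system <- match.arg(marker_system)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  genotype_table(df, marker_system)
}

#' Write a genotype table as TSV
#'
#' Missing values are written as the sentinel ".".  A write/read round trip
#' reproduces all analysed fields.
#'
#' @param x a genotype table.
#' @param path output path.
#' @export
write_genotype_table <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    v <- as.character(df[[j]])
    v[is.na(v) | v == ""] <- MISSING_TOKEN
    df[[j]] <- v
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive the DYS389b repeat count
#'
#' DYS389b is not typed directly: its repeat count is the difference
#' DYS389II - DYS389I.  The derived locus replaces DYS389II in the analysis
#' profile while DYS389I is retained.
#'
#' @param x a genotype table containing DYS389I and DYS389II.
#' @return the table with a DYS389b column; DYS389II is dropped from the
#'   analysis STR set (the raw column is kept).
#' @export
derive_dys389b <- function(x) {
  for (col in c("DYS389I", "DYS389II")) {
    if (!col %in% names(x)) stop("schema error: column '", col, "' required")
  }
  b <- x$DYS389II - x$DYS389I
  bad <- which(!is.na(b) & b < 0)
  if (length(bad)) {
    stop("validation error: DYS389II < DYS389I at row ", bad[1])
  }
  if (any(!is.na(b) & b == 0)) {
    warning("DYS389b = 0 for ", sum(b == 0, na.rm = TRUE),
            " individual(s); flagged as suspicious")
  }
  x$DYS389b <- as.integer(b)
  loci <- union(setdiff(str_loci(x), "DYS389II"), "DYS389b")
  attr(x, "str_loci") <- loci
  x
}

#' Length of an inclusive clockwise arc on a circular genome
#'
#' mtDNA coordinates are 1-based and circular; the typed control-region
#' window runs clockwise from 15975 through the origin to 155, a 750-bp arc
#' on the 16569-bp rCRS circle.
#'
#' @param start,end 1-based positions.
#' @param genome_length circle length (rCRS: 16569).
#' @return integer arc length, counting both endpoints.
#' @export
circular_region_length <- function(start, end,
                                   genome_length = MT_GENOME_LENGTH) {
  for (p in c(start, end)) {
    if (p < 1 || p > genome_length) {
      stop("position ", p, " outside 1..", genome_length)
    }
  }
  if (end >= start) as.integer(end - start + 1)
  else as.integer(genome_length - start + 1 + end)
}

#' Read a haplogroup tree configuration
#'
#' Tab-separated text with a header and columns `label`, `parent`,
#' `reduced`; `parent` is "." for a root, `reduced` is 1 for nodes that form
#' the reduced cross-study comparison level.
#'
#' @param path file path.
#' @return a `haplogroup_tree` list with elements `parent` (named character)
#'   and `reduced` (character vector).
#' @export
read_haplogroup_tree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("label", "parent", "reduced") %in% names(df)))
  if (anyDuplicated(df$label)) {
    stop("duplicate haplogroup label in tree: ",
         df$label[duplicated(df$label)][1])
  }
  parent <- stats::setNames(df$parent, df$label)
  parent[parent == MISSING_TOKEN] <- NA
  haplogroup_tree(parent, df$label[df$reduced == 1])
}

#' Build a haplogroup tree object
#' @param parent named character vector mapping child label to parent label
#'   (NA for roots).
#' @param reduced labels forming the reduced comparison level.
#' @export
haplogroup_tree <- function(parent, reduced) {
  known <- names(parent)
  up <- parent[!is.na(parent)]
  unknown <- setdiff(unname(up), known)
  if (length(unknown)) {
    stop("tree refers to unknown parent label(s): ",
         paste(unknown, collapse = ", "))
  }
  missing_red <- setdiff(reduced, known)
  if (length(missing_red)) {
    stop("reduced-level label(s) absent from tree: ",
         paste(missing_red, collapse = ", "))
  }
  structure(list(parent = parent, reduced = reduced),
            class = "haplogroup_tree")
}

#' Map a haplogroup label to its reduced-level ancestor
#' @param label haplogroup label(s).
#' @param tree a `haplogroup_tree`.
#' @return the reduced-level label for each input label.
#' @export
reduced_ancestor <- function(label, tree) {
  vapply(label, function(lb) {
    if (!lb %in% names(tree$parent)) {
      stop("mapping error: label '", lb, "' not in haplogroup tree")
    }
    cur <- lb
    for (i in seq_len(length(tree$parent) + 1L)) {
      if (cur %in% tree$reduced) return(cur)
      nxt <- tree$parent[[cur]]
      if (is.na(nxt)) {
        stop("mapping error: label '", lb,
             "' has no reduced-level ancestor")
      }
      cur <- nxt
    }
    stop("cycle detected in haplogroup tree at '", lb, "'")
  }, character(1))
}

#' Collapse a frequency table to the reduced haplogroup level
#'
#' Sub-haplogroup counts are summed into their designated reduced-level
#' ancestors so that tables typed at different resolutions can be compared;
#' row totals are preserved exactly.
#'
#' @param counts populations x haplogroups integer matrix.
#' @param tree a `haplogroup_tree`.
#' @return collapsed count matrix with reduced-level column labels.
#' @export
collapse_haplogroups <- function(counts, tree) {
  counts <- as.matrix(counts)
  map <- reduced_ancestor(colnames(counts), tree)
  collapsed <- t(rowsum(t(counts), group = map))
  # keep reduced-level ordering as first encountered
  collapsed[, unique(unname(map)), drop = FALSE]
}

#' Read a mutation-rate / clock configuration
#'
#' YAML with fields `generation_years` (years per generation),
#' `hvs_rate_years_per_mutation` (years per HVS-I mutation, e.g. a
#' Soares-style calibration; no default is assumed), `dating_loci` (the 8
#' Y-STR loci used for variance dating) and `locus_rates` (mutations per
#' locus per generation, e.g. Ballantyne-scale pedigree rates).
#'
#' @param path file path.
#' @return a `clock_config` list.
#' @export
read_clock_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  clock_config(generation_years = cfg$generation_years,
               hvs_rate_years_per_mutation = cfg$hvs_rate_years_per_mutation,
               dating_loci = unlist(cfg$dating_loci),
               locus_rates = unlist(cfg$locus_rates))
}

#' Build a clock configuration
#' @param generation_years years per generation (> 0).
#' @param hvs_rate_years_per_mutation years per HVS-I mutation (> 0), or NULL
#'   if no mtDNA dating is intended.
#' @param dating_loci ordered character vector of 8 Y-STR loci.
#' @param locus_rates named numeric vector, mutations/locus/generation.
#' @export
clock_config <- function(generation_years = 25,
                         hvs_rate_years_per_mutation = NULL,
                         dating_loci = NULL, locus_rates = NULL) {
  if (!is.numeric(generation_years) || generation_years <= 0) {
    stop("config error: generation_years must be > 0")
  }
  if (!is.null(hvs_rate_years_per_mutation) &&
      hvs_rate_years_per_mutation <= 0) {
    stop("config error: hvs_rate_years_per_mutation must be > 0")
  }
  if (!is.null(locus_rates) && any(locus_rates <= 0)) {
    stop("config error: all locus rates must be > 0")
  }
  if (!is.null(dating_loci)) {
    miss <- setdiff(dating_loci, names(locus_rates))
    if (length(miss)) {
      stop("config error: no mutation rate for dating locus ",
           paste(miss, collapse = ", "))
    }
  }
  structure(list(generation_years = generation_years,
                 hvs_rate_years_per_mutation = hvs_rate_years_per_mutation,
                 dating_loci = dating_loci, locus_rates = locus_rates),
            class = "clock_config")
}
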