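# Readers/writers for the on-disk formats the pipeline touches:
# peptide quantification tables (TSV/CSV), protein FASTA (decoy
# generation), GMT gene sets, Newick dendrograms, and a YAML config.

#' Read and validate a peptide quantification table
#'
#' Expects a delimited file with header columns `peptide`, `protein`,
#' `unique` (0/1 or logical), `run`, `intensity`, and optionally the
#' pair `mz_theoretical`, `mz_observed`. Missing values are encoded by
#' row absence: any non-positive or non-numeric intensity is an error,
#' as is a run id absent from the design or a duplicated
#' (peptide, protein, run) triplet.
#'
#' @param path File path; delimiter auto-detected from the extension
#'   (`.tsv` = tab, `.csv` = comma) unless `delim` is given.
#' @param design A [study_design()] whose run ids the `run` column must
#'   match.
#' @param delim Optional explicit field delimiter.
#' @return The validated data.frame of peptide measurements, with the
#'   number of accepted rows as attribute `"n_accepted"`.
#' @export
read_peptide_table <- function(path, design, delim = NULL) {
  design <- if (inherits(design, "study_design")) design else study_design(design)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  tbl <- as.data.frame(data.table::fread(path, sep = delim, header = TRUE,
                                         colClasses = list(character = "run")))
  mandatory <- c("peptide", "protein", "unique", "run", "intensity")
  absent <- setdiff(mandatory, names(tbl))
  if (length(absent) > 0L) {
    stop("peptide table is missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  }
  has_mass <- c("mz_theoretical", "mz_observed") %in% names(tbl)
  if (xor(has_mass[1], has_mass[2])) {
    stop("mz_theoretical and mz_observed must be present together or not at all")
  }

  intensity <- suppressWarnings(as.numeric(tbl$intensity))
  bad <- which(is.na(intensity) | intensity <= 0)
  if (length(bad) > 0L) {
    stop("non-positive or non-numeric intensity on row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         " (missing values must be absent rows, not zeros)")
  }
  tbl$intensity <- intensity

  unknown_runs <- setdiff(unique(tbl$run), design$run_id)
  if (length(unknown_runs) > 0L) {
    stop("run id(s) not in the study design: ",
         paste(unknown_runs, collapse = ", "))
  }

  key <- paste(tbl$peptide, tbl$protein, tbl$run, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    d <- tbl[dup[1L], ]
    stop("duplicate (peptide, protein, run) key: (",
         d$peptide, ", ", d$protein, ", ", d$run, ")")
  }

  if (all(has_mass)) {
    if (any(tbl$mz_theoretical <= 0) || any(tbl$mz_observed <= 0)) {
      stop("masses must be positive")
    }
  }
  tbl$unique <- as.logical(tbl$unique)
  attr(tbl, "n_accepted") <- nrow(tbl)
  tbl
}

#' Write a peptide table as TSV
#'
#' @param tbl A peptide measurement data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_peptide_table <- function(tbl, path) {
  data.table::fwrite(tbl, path, sep = "\t")
  invisible(path)
}

#' Append reversed-decoy records to a protein FASTA
#'
#' For each record, emits an additional record with the amino-acid
#' sequence reversed and the id prefixed (default `"REV_"`). Reversed
#' decoys are the standard device for estimating false identifications;
#' the filter cascade later discards any protein carrying the prefix.
#'
#' @param fasta_path Input protein FASTA.
#' @param out_path Optional output FASTA path.
#' @param prefix Decoy id prefix (default `"REV_"`).
#' @return A `Biostrings::BStringSet` with original records followed by
#'   their reversed decoys (2x the input count); written to `out_path`
#'   if given.
#' @export
make_reversed_decoys <- function(fasta_path, out_path = NULL, prefix = "REV_") {
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  rev_seqs <- Biostrings::reverse(seqs)
  names(rev_seqs) <- paste0(prefix, ids)
  out <- c(seqs, rev_seqs)
  names(out) <- c(ids, names(rev_seqs))
  if (anyDuplicated(names(out))) {
    stop("decoy id collision after prefixing: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  }
  if (!is.null(out_path)) {
    Biostrings::writeXStringSet(out, out_path)
  }
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `id`, `description`,
#' then member ids. Members are deduplicated within a set; lines with
#' fewer than three fields are skipped with a warning.
#'
#' @param path GMT file path.
#' @return A list of class `"gene_set_collection"` with elements
#'   `set_id`, `description` and `members` (a named list of character
#'   vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(character(0), character(0), list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short)) {
    warning("skipped ", sum(short), " GMT line(s) with fewer than 3 fields: line(s) ",
            paste(which(short), collapse = ", "))
    fields <- fields[!short]
  }
  if (length(fields) == 0L) {
    return(gene_set_collection(character(0), character(0), list()))
  }
  set_id <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(set_id)) {
    stop("duplicate set id(s) in GMT: ",
         paste(unique(set_id[duplicated(set_id)]), collapse = ", "))
  }
  description <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  gene_set_collection(set_id, description, members)
}

gene_set_collection <- function(set_id, description, members) {
  names(members) <- set_id
  out <- list(set_id = set_id, description = stats::setNames(description, set_id),
              members = members)
  class(out) <- "gene_set_collection"
  out
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x$set_id), "sets\n")
  if (length(x$set_id) > 0L) {
    sizes <- lengths(x$members)
    cat(sprintf("  member counts: min %d, median %.0f, max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  }
  invisible(x)
}

newick_quote <- function(label) {
  needs <- grepl("[][ \t(),:;']", label)
  label[needs] <- paste0("'", gsub("'", "''", label[needs]), "'")
  label
}

#' Serialize an hclust dendrogram as a Newick string
#'
#' Produces an ultrametric Newick tree whose branch lengths are
#' merge-height differences (a leaf's branch length equals the height of
#' the merge that absorbs it). Labels containing Newick metacharacters
#' are single-quoted.
#'
#' @param hc An `hclust` object with at least 2 leaves.
#' @return A single Newick string terminated by `";"`.
#' @export
write_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$labels)
  if (n < 2L) stop("dendrogram must have at least 2 leaves")
  labels <- newick_quote(hc$labels)
  node_str <- function(i, parent_height) {
    if (i < 0L) {      # leaf: hclust encodes leaves as negative indices
      sprintf("%s:%s", labels[-i], format(parent_height, digits = 15))
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%s",
              node_str(hc$merge[i, 1L], h),
              node_str(hc$merge[i, 2L], h),
              format(parent_height - h, digits = 15))
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  paste0("(", node_str(hc$merge[root, 1L], h), ",",
         node_str(hc$merge[root, 2L], h), ");")
}

#' Read a pipeline configuration file
#'
#' YAML file with optional blocks `design` (list of runs with `run_id`,
#' `condition`, `replicate`), `sim_params` and `thresholds`
#' (argument lists for [sim_params()] and [filter_thresholds()]).
#'
#' @param path YAML config path.
#' @return A list with `design`, `sim_params`, `thresholds` (each NULL
#'   when absent from the file) and any further top-level entries.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- cfg
  if (!is.null(cfg$design)) {
    out$design <- study_design(do.call(rbind, lapply(cfg$design, as.data.frame)))
  }
  if (!is.null(cfg$sim_params)) {
    out$sim_params <- do.call(sim_params, cfg$sim_params)
  }
  if (!is.null(cfg$thresholds)) {
    out$thresholds <- do.call(filter_thresholds, cfg$thresholds)
  }
  out
}
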