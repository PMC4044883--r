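# Feature tables and native sequence-composition features.
#
# The canonical schema has 48 features: 17 composition features (16
# dinucleotide frequencies + G+C ratio) computed natively from FASTA, and
# 31 folding/thermodynamic features (dP, dG, zG, NEFE, MFEI1..4, ...) that
# require an RNA secondary-structure engine and are consumed as
# precomputed columns.

RNA_BASES <- c("A", "C", "G", "U")

#' Canonical 48-feature registry
#'
#' Names and provenance of the full feature schema.  `computed = TRUE`
#' marks the 17 composition features this package derives from sequence;
#' the remaining 31 folding/thermodynamic features are accepted as
#' externally computed columns (see [merge_external_features()]).
#'
#' @return a data.frame with columns `name`, `group`, `computed`.
#' @export
feature_registry <- function() {
  dinuc <- as.vector(t(outer(RNA_BASES, RNA_BASES, paste0)))
  comp <- c(dinuc, "GC_ratio")
  folding <- c("dP", "dG", "dQ", "dD", "dF",
               "MFEI1", "MFEI2", "zP", "zG", "zQ", "zD", "zF")
  thermo <- c("MFEI3", "MFEI4", "NEFE", "Freq", "Diversity", "Diff",
              "dS", "dS_L", "dH", "dH_L", "Tm", "Tm_L",
              "AU_L", "GC_L", "GU_L", "avg_bp_stem",
              "pct_AU_nstems", "pct_GC_nstems", "pct_GU_nstems")
  data.frame(
    name = c(comp, folding, thermo),
    group = c(rep("composition", length(comp)),
              rep("folding", length(folding)),
              rep("thermodynamic", length(thermo))),
    computed = c(rep(TRUE, length(comp)),
                 rep(FALSE, length(folding) + length(thermo))),
    stringsAsFactors = FALSE
  )
}

#' Validate a feature table
#'
#' A feature table is a data.frame with a character `id` column, numeric
#' feature columns and a binary `label` column (1 = pre-miRNA).
#'
#' @param df a data.frame.
#' @return the validated data.frame (invisibly unchanged) with class
#'   retained as a plain data.frame.
#' @export
feature_table <- function(df) {
  df <- as.data.frame(df)
  if (!all(c("id", "label") %in% names(df))) {
    stop("a feature table needs 'id' and 'label' columns")
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("feature table ids must be unique")
  df$label <- as_binary_labels(df$label)
  feats <- setdiff(names(df), c("id", "label"))
  if (anyDuplicated(feats)) stop("feature names must be unique")
  for (f in feats) {
    if (!is.numeric(df[[f]])) {
      stop("feature column '", f, "' is not numeric")
    }
  }
  df
}

#' @rdname feature_table
#' @param table a feature table.
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("id", "label"))
}

#' Read hairpin sequences from FASTA
#'
#' Record ids are taken from the header up to the first whitespace;
#' sequences are upper-cased and `T` is normalized to `U`.  Residues
#' outside `A/C/G/U` after normalization are rejected, naming the record.
#'
#' @param path FASTA file.
#' @return a [Biostrings::RNAStringSet] named by record id.
#' @export
read_hairpin_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(raw))
  seqs <- chartr("Tt", "Uu", toupper(as.character(raw)))
  bad <- gsub("[ACGU]", "", seqs)
  if (any(nchar(bad) > 0L)) {
    i <- which(nchar(bad) > 0L)[1L]
    stop("record '", ids[i], "' contains illegal residue(s) '",
         substr(bad[i], 1L, 1L), "' after T->U normalization")
  }
  out <- Biostrings::RNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write hairpin sequences to FASTA
#'
#' @param seqs an [Biostrings::RNAStringSet].
#' @param path output file.
#' @export
write_hairpin_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Dinucleotide frequencies
#'
#' Counts of each of the 16 ordered base pairs over the `L - 1` overlapping
#' windows, divided by `L - 1`; the 16 values sum to one.
#'
#' @param seqs an [Biostrings::RNAStringSet] (every sequence must have
#'   length >= 2).
#' @return numeric matrix, one row per sequence, 16 named columns.
#' @export
dinucleotide_frequencies <- function(seqs) {
  seqs <- as_rna_set(seqs)
  if (any(Biostrings::width(seqs) < 2L)) {
    stop("dinucleotide frequencies need sequences of length >= 2")
  }
  f <- Biostrings::dinucleotideFrequency(seqs, as.prob = TRUE)
  rownames(f) <- names(seqs)
  f
}

#' G+C content
#'
#' @param seqs an [Biostrings::RNAStringSet].
#' @return named numeric vector of `(#G + #C) / L`.
#' @export
gc_ratio <- function(seqs) {
  seqs <- as_rna_set(seqs)
  v <- as.vector(Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE))
  names(v) <- names(seqs)
  v
}

as_rna_set <- function(seqs) {
  if (is.character(seqs)) {
    seqs <- Biostrings::RNAStringSet(chartr("Tt", "Uu", toupper(seqs)))
  }
  if (inherits(seqs, "RNAString")) seqs <- Biostrings::RNAStringSet(seqs)
  stopifnot(inherits(seqs, "RNAStringSet"))
  seqs
}

#' Composition feature table from sequences
#'
#' The 17 natively computable features: 16 dinucleotide frequencies and the
#' G+C ratio.  Labels default to `NA`-free zeros and are normally attached
#' afterwards or via `labels`.
#'
#' @param seqs an [Biostrings::RNAStringSet] (e.g. from
#'   [read_hairpin_fasta()]).
#' @param labels optional binary labels, one per sequence.
#' @return a feature table data.frame (`id`, 17 features, `label`).
#' @export
composition_features <- function(seqs, labels = NULL) {
  seqs <- as_rna_set(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  f <- dinucleotide_frequencies(seqs)
  df <- data.frame(id = ids, f, GC_ratio = gc_ratio(seqs),
                   label = if (is.null(labels)) 0L else
                     as_binary_labels(labels),
                   row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
  feature_table(df)
}

#' Merge externally computed feature columns
#'
#' Joins a table of externally computed features (e.g. the 31
#' folding/thermodynamic columns) onto a base table by `id`, preserving the
#' base row order.  Column collisions are an error; feature names absent
#' from the canonical registry trigger a warning but are kept.
#'
#' @param base,extra feature tables sharing the same id set (`extra` may
#'   omit the `label` column; if present it must agree with `base`).
#' @return the joined feature table.
#' @export
merge_external_features <- function(base, extra) {
  base <- feature_table(base)
  extra <- as.data.frame(extra)
  if (!"id" %in% names(extra)) stop("extra table needs an 'id' column")
  extra$id <- as.character(extra$id)
  if (ncol(extra) == 1L) return(base)

  missing <- setdiff(base$id, extra$id)
  surplus <- setdiff(extra$id, base$id)
  if (length(missing) || length(surplus)) {
    stop("id mismatch between tables; missing from extra: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(surplus)) paste0("; unknown ids: ",
           paste(utils::head(surplus, 5L), collapse = ", ")))
  }
  if ("label" %in% names(extra)) {
    ord0 <- match(base$id, extra$id)
    if (!identical(as_binary_labels(extra$label[ord0]),
                   base$label)) {
      stop("label columns disagree between tables")
    }
    extra$label <- NULL
  }
  clash <- intersect(feature_names(base), setdiff(names(extra), "id"))
  if (length(clash)) {
    stop("column name collision: ", paste(clash, collapse = ", "))
  }
  newcols <- setdiff(names(extra), "id")
  unknown <- setdiff(newcols, feature_registry()$name)
  if (length(unknown)) {
    warning("feature name(s) not in the canonical 48-feature registry: ",
            paste(unknown, collapse = ", "))
  }
  ord <- match(base$id, extra$id)
  out <- cbind(base[setdiff(names(base), "label")],
               extra[ord, newcols, drop = FALSE],
               label = base$label)
  rownames(out) <- NULL
  feature_table(out)
}

#' Read / write delimited feature tables
#'
#' Plain UTF-8 delimited text with a mandatory header, an `id` column, a
#' binary `label` column and `.` as decimal mark.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @return `read_feature_table()` returns a validated feature table.
#' @export
read_feature_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  feature_table(df)
}

#' @rdname read_feature_table
#' @param table a feature table.
#' @export
write_feature_table <- function(table, path, sep = "\t") {
  table <- feature_table(table)
  utils::write.table(table, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Published benchmark composition
#'
#' Sample counts of the standard human benchmark this package is designed
#' around: 691 non-redundant pre-miRNA hairpins versus 8,494 pseudo
#' hairpins plus 754 other non-coding RNAs (ratio about 1:13).
#'
#' @return a list with `positives`, `pseudo_hairpins`, and the `ncrna`
#'   subcategory counts.
#' @export
benchmark_counts <- function() {
  list(
    positives = 691L,
    pseudo_hairpins = 8494L,
    ncrna = c(snoRNA = 334L, tRNA = 327L, snRNA = 53L, YRNA = 32L,
              rRNA_5S = 5L, other = 3L)
  )
}
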