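#' Read sequences from a FASTA file
#'
#' Reads a (optionally gzip-compressed) FASTA file into a tibble of sequence
#' records. Amino-acid records are validated against the 20 standard residues
#' plus the degenerate codes `X`, `B`, `Z` and `U`; anything else is rejected.
#'
#' @param path Path to a FASTA file (plain or `.gz`).
#' @param alphabet `"aa"` (default) validates amino-acid residues; `"dna"`
#'   validates `ACGTN`; `"any"` skips alphabet validation.
#' @return A tibble with columns `id`, `seq` and `description`. Record order
#'   is preserved and multi-line sequences are concatenated.
#' @export
read_fasta <- function(path, alphabet = c("aa", "dna", "any")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop_earminer(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_earminer(sprintf("empty FASTA file: %s", path))
  full <- names(set)
  id <- stringr::str_extract(full, "^\\S+")
  description <- stringr::str_trim(stringr::str_remove(full, "^\\S+"))
  if (anyNA(id) || any(!nzchar(id))) stop_earminer("FASTA record with empty id")
  dup <- id[duplicated(id)]
  if (length(dup)) {
    stop_earminer(sprintf("duplicate FASTA id: %s", dup[[1]]),
                  class = "earminer_duplicate_id")
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop_earminer(sprintf("empty sequence for record %s", id[!nzchar(seqs)][[1]]))
  }
  if (alphabet == "aa") {
    purrr::walk2(seqs, id, ~ assert_aa_seq(.x, sprintf("record '%s'", .y)))
  } else if (alphabet == "dna") {
    bad <- stringr::str_detect(seqs, "[^ACGTN]")
    if (any(bad)) {
      stop_earminer(sprintf("non-ACGTN residue in record %s", id[bad][[1]]))
    }
  }
  tibble(id = unname(id), seq = unname(seqs), description = unname(description))
}

#' Write sequence records to a FASTA file
#'
#' @param records Tibble with columns `id`, `seq` and optionally `description`.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  if (anyDuplicated(records$id)) stop_earminer("duplicate ids in records")
  set <- Biostrings::BStringSet(records$seq)
  desc <- if ("description" %in% names(records)) records$description
          else rep("", nrow(records))
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# split non-comment lines of a text table, remembering original line numbers
read_table_lines <- function(path, skip_empty = TRUE) {
  if (!file.exists(path)) stop_earminer(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !stringr::str_starts(lines, "#")
  if (skip_empty) keep <- keep & nzchar(stringr::str_trim(lines))
  list(lines = lines[keep], lineno = which(keep))
}

malformed <- function(path, lineno, why) {
  stop_earminer(sprintf("%s line %d: %s", path, lineno, why),
                class = "earminer_parse_error")
}

#' Read gene models from a GFF3 file
#'
#' Keeps `gene` features only. Coordinates are converted from GFF3's 1-based
#' closed convention to a tibble that records both the original 1-based
#' `start`/`end` and the strand-aware transcription start site `tss`
#' (`start` on `+`, `end` on `-`).
#'
#' @param path Path to a GFF3 file (plain or `.gz`).
#' @return Tibble with columns `gene_id`, `seq_id`, `strand`, `start`, `end`,
#'   `tss` (all 1-based closed).
#' @export
read_gff_genes <- function(path) {
  tl <- read_table_lines(path)
  rows <- purrr::map2(tl$lines, tl$lineno, function(line, no) {
    f <- stringr::str_split_1(line, "\t")
    if (length(f) < 9) malformed(path, no, "fewer than 9 GFF3 columns")
    if (tolower(f[[3]]) != "gene") return(NULL)
    start <- suppressWarnings(as.integer(f[[4]]))
    end <- suppressWarnings(as.integer(f[[5]]))
    if (is.na(start) || is.na(end)) malformed(path, no, "non-numeric coordinates")
    if (start > end) malformed(path, no, sprintf("start %d > end %d", start, end))
    strand <- f[[7]]
    if (!strand %in% c("+", "-")) {
      malformed(path, no, sprintf("unknown strand '%s'", strand))
    }
    gid <- stringr::str_match(f[[9]], "ID=([^;]+)")[, 2]
    if (is.na(gid)) gid <- stringr::str_trim(f[[9]])
    tibble(gene_id = gid, seq_id = f[[1]], strand = strand,
           start = start, end = end,
           tss = if (strand == "+") start else end)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(gene_id = character(), seq_id = character(),
                  strand = character(), start = integer(), end = integer(),
                  tss = integer()))
  }
  out
}

#' Read genomic intervals from a BED file
#'
#' BED coordinates are 0-based half-open and are preserved exactly as read.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `seq_id`, `start`, `end`, `name`, `mark`
#'   (columns 4 and 5-/6-absent fields filled with `NA`).
#' @export
read_bed <- function(path) {
  tl <- read_table_lines(path)
  rows <- purrr::map2(tl$lines, tl$lineno, function(line, no) {
    f <- stringr::str_split_1(line, "\t")
    if (length(f) < 3) malformed(path, no, "fewer than 3 BED columns")
    start <- suppressWarnings(as.integer(f[[2]]))
    end <- suppressWarnings(as.integer(f[[3]]))
    if (is.na(start) || is.na(end)) malformed(path, no, "non-numeric coordinates")
    if (start < 0) malformed(path, no, "negative start")
    if (start >= end) malformed(path, no, sprintf("start %d >= end %d", start, end))
    tibble(seq_id = f[[1]], start = start, end = end,
           name = if (length(f) >= 4) f[[4]] else NA_character_,
           mark = if (length(f) >= 5) f[[5]] else NA_character_)
  })
  bind_rows(rows)
}

#' Read a gene-set collection from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @return Tibble with one row per set: `set`, `description` and a
#'   list-column `genes`.
#' @export
read_gmt <- function(path) {
  tl <- read_table_lines(path)
  rows <- purrr::map2(tl$lines, tl$lineno, function(line, no) {
    f <- stringr::str_split_1(line, "\t")
    if (length(f) < 3) malformed(path, no, "GMT line needs name, description and >= 1 gene")
    genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(genes) == 0L) malformed(path, no, "gene set with no members")
    tibble(set = f[[1]], description = f[[2]], genes = list(genes))
  })
  out <- bind_rows(rows)
  dup <- out$set[duplicated(out$set)]
  if (length(dup)) stop_earminer(sprintf("duplicate gene-set name: %s", dup[[1]]))
  out
}

#' Write a gene-set collection to a GMT file
#' @param sets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(sets, function(set, description, genes, ...) {
    paste(c(set, description, genes), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read an undirected edge list from a TSV file
#'
#' Lines are `nodeA<TAB>nodeB[<TAB>weight]`. Self-loops and duplicate
#' (unordered) edges are rejected.
#'
#' @param path Path to the edge list.
#' @return An edge tibble with columns `from`, `to`, `weight` (`from < to`
#'   lexicographically).
#' @export
read_edge_list <- function(path) {
  tl <- read_table_lines(path)
  rows <- purrr::map2(tl$lines, tl$lineno, function(line, no) {
    f <- stringr::str_split_1(line, "\t")
    if (length(f) < 2) malformed(path, no, "edge needs two node columns")
    if (f[[1]] == f[[2]]) malformed(path, no, sprintf("self-loop on '%s'", f[[1]]))
    w <- if (length(f) >= 3) suppressWarnings(as.double(f[[3]])) else NA_real_
    if (length(f) >= 3 && is.na(w)) malformed(path, no, "non-numeric weight")
    tibble(from = min(f[[1]], f[[2]]), to = max(f[[1]], f[[2]]), weight = w)
  })
  out <- bind_rows(rows)
  dup <- duplicated(out[, c("from", "to")])
  if (any(dup)) {
    malformed(path, tl$lineno[which(dup)[[1]]],
              sprintf("duplicate edge %s--%s", out$from[dup][[1]], out$to[dup][[1]]))
  }
  out
}

#' Write an edge list to a TSV file
#' @param edges Edge tibble (`from`, `to`, optional `weight`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  w <- edges$weight %||% rep(NA_real_, nrow(edges))
  lines <- ifelse(is.na(w),
                  paste(edges$from, edges$to, sep = "\t"),
                  paste(edges$from, edges$to, w, sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a cis-element motif table
#'
#' Lines are `name<TAB>regular-expression` over the nucleotide alphabet.
#' Every pattern is compiled at read time; a pattern that fails to compile
#' is rejected with the motif's name.
#'
#' @param path Path to the motif TSV.
#' @return Tibble with columns `motif` and `pattern`.
#' @export
read_motif_table <- function(path) {
  tl <- read_table_lines(path)
  rows <- purrr::map2(tl$lines, tl$lineno, function(line, no) {
    f <- stringr::str_split_1(line, "\t")
    if (length(f) < 2) malformed(path, no, "motif line needs name and pattern")
    ok <- tryCatch({
      stringr::str_detect("ACGT", stringr::regex(f[[2]])); TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      stop_earminer(sprintf("motif '%s': pattern '%s' fails to compile", f[[1]], f[[2]]),
                    class = "earminer_parse_error")
    }
    tibble(motif = f[[1]], pattern = f[[2]])
  })
  bind_rows(rows)
}

#' Read an expression matrix from TSV
#'
#' First column holds gene ids, the header row sample ids.
#'
#' @param path Path to the TSV.
#' @return A numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression_matrix <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(tb) < 2) stop_earminer("expression matrix needs gene id + >= 1 sample column")
  ids <- as.character(tb[[1]])
  if (anyDuplicated(ids)) stop_earminer("duplicate gene ids in expression matrix")
  m <- as.matrix(tb[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_earminer("non-numeric expression values")
  rownames(m) <- ids
  m
}
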