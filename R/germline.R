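#' Germline gene databases
#'
#' A germline database is a tibble with one row per germline allele and
#' columns `name` (allele identifier, e.g. `"IGHV1-18*01"`), `gene` (the name
#' with the `*NN` allele suffix stripped), `segment` (`"V"`, `"D"` or `"J"`),
#' `sequence` (ungapped uppercase DNA) and `motif_anchor` (0-based index of
#' the conserved motif start within the sequence; `NA` for D genes and for
#' V/J genes lacking the motif, which are handled only by fallback
#' alignment). The V motif is `TATTACTGT`, the J motif `CTGGGG`; the anchor
#' is the 3'-most exact occurrence.
#'
#' @name germline_db
NULL

new_germline_db <- function(tbl, source_label = "") {
  tbl <- as_tibble(tbl)
  structure(tbl, source_label = source_label,
            class = c("germline_db", class(tbl)))
}

validate_germline_db <- function(db) {
  stopifnot(all(c("name", "gene", "segment", "sequence", "motif_anchor")
                %in% names(db)))
  dup <- db |>
    dplyr::count(.data$segment, .data$name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0)
    stop("duplicate germline names within a segment class: ",
         paste(dup$name, collapse = ", "), call. = FALSE)
  if (any(nchar(db$sequence) == 0))
    stop("empty germline sequence after normalization", call. = FALSE)
  invisible(db)
}

strip_allele <- function(name) sub("\\*.*$", "", name)

# 3'-most exact occurrence of motif, 0-based; NA if absent
motif_anchor_of <- function(sequence, motif) {
  hits <- stringr::str_locate_all(sequence, stringr::fixed(motif))[[1]]
  if (nrow(hits) == 0) return(NA_integer_)
  as.integer(hits[nrow(hits), "start"] - 1L)
}

segment_of <- function(name) {
  m <- stringr::str_match(name, "^IGH([VDJ])")[, 2]
  m
}

#' Read a germline V/D/J database from FASTA
#'
#' Reads plain FASTA or the IMGT gapped dialect (in which `.` marks an
#' IMGT-numbering gap). IMGT headers are pipe-delimited with the allele name
#' in the second field; plain headers use the first whitespace-delimited
#' token. Gap characters are stripped, sequences uppercased, the segment
#' class inferred from the name (`IGHV...` -> V, etc.; records with an
#' unrecognizable class are skipped with a warning) and motif anchors located
#' (3'-most exact occurrence; V/J genes without the motif are retained with
#' `motif_anchor = NA`).
#'
#' @param path Path to a FASTA file, or a directory of `.fasta`/`.fa` files.
#' @param dialect `"auto"` (default), `"imgt_gapped"` or `"plain_fasta"`.
#' @return A [germline_db] tibble.
#' @export
read_germlines <- function(path, dialect = c("auto", "imgt_gapped",
                                             "plain_fasta")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  files <- path
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    if (length(files) == 0)
      stop("no FASTA files in directory: ", path, call. = FALSE)
  }
  seqs <- tryCatch(
    do.call(c, lapply(files, Biostrings::readBStringSet)),
    error = function(e) stop("unparseable FASTA: ", conditionMessage(e),
                             call. = FALSE))
  if (length(seqs) == 0) {
    warning("empty germline database: ", path, call. = FALSE)
    return(new_germline_db(
      tibble(name = character(), gene = character(), segment = character(),
             sequence = character(), motif_anchor = integer()),
      source_label = path))
  }
  headers <- names(seqs)
  allele <- ifelse(grepl("|", headers, fixed = TRUE),
                   vapply(strsplit(headers, "|", fixed = TRUE), `[`, "", 2),
                   vapply(strsplit(headers, "\\s+"), `[`, "", 1))
  raw <- unname(as.character(seqs))
  stripped <- toupper(gsub("[.\\-]", "", raw))
  if (dialect == "plain_fasta" && any(grepl("[.]", raw, fixed = FALSE)))
    stop("gap characters found but dialect is plain_fasta", call. = FALSE)
  bad_alpha <- grepl("[^ACGTN]", stripped)
  if (any(bad_alpha))
    stop("ambiguity characters other than N in: ",
         paste(allele[bad_alpha], collapse = ", "), call. = FALSE)
  seg <- segment_of(allele)
  if (anyNA(seg)) {
    warning("skipping records with unrecognizable segment class: ",
            paste(allele[is.na(seg)], collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(seg) & nchar(stripped) > 0
  db <- tibble(
    name = allele[keep],
    gene = strip_allele(allele[keep]),
    segment = seg[keep],
    sequence = stripped[keep],
    motif_anchor = vapply(seq_len(sum(keep)), function(i) {
      s <- seg[keep][i]
      if (s == "V") motif_anchor_of(stripped[keep][i], V_MOTIF)
      else if (s == "J") motif_anchor_of(stripped[keep][i], J_MOTIF)
      else NA_integer_
    }, integer(1)))
  db <- new_germline_db(db, source_label = path)
  validate_germline_db(db)
  db
}

#' Write a germline database to plain FASTA
#'
#' @param db A [germline_db].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_germlines <- function(db, path) {
  set <- Biostrings::BStringSet(setNames(db$sequence, db$name))
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

#' Generate a synthetic germline database fixture
#'
#' Builds a deterministic, fully synthetic V/D/J database with the structural
#' features the partitioner relies on: every V is 290 nt with exactly one
#' `TATTACTGT` near the 3' end (8 trailing bases, mirroring the short
#' framework tail 3' of the Tyr-Tyr-Cys codons in real IGHV genes), every J
#' is 50 nt with exactly one `CTGGGG`, and D genes are 10-35 nt without
#' either motif. Distinct genes of the same class are rejection-sampled to
#' share < 80% identity over a global alignment, so assignments are
#' unambiguous at low mutation.
#'
#' @param n_v,n_d,n_j Number of genes per class (>= 1).
#' @param seed Integer seed; the database is byte-identical for a fixed seed.
#' @param n_alleles_v If > 1, the first V gene receives additional alleles
#'   (`*02`, ...) differing by one substitution each.
#' @return A [germline_db].
#' @examples
#' db <- make_fixture_db(3, 2, 2, seed = 1)
#' @export
make_fixture_db <- function(n_v = 12, n_d = 8, n_j = 4, seed = 1,
                            n_alleles_v = 1) {
  stopifnot(n_v >= 1, n_d >= 1, n_j >= 1, n_alleles_v >= 1)
  with_seed(seed, function() {
    scheme <- scoring_scheme()
    count_hits <- function(s, motif)
      nrow(stringr::str_locate_all(s, stringr::fixed(motif))[[1]])
    too_similar <- function(s, accepted) {
      if (length(accepted) == 0) return(FALSE)
      any(vapply(accepted, function(a) {
        al <- full_overlap_dp(s, a, scheme)
        al$n_match / min(nchar(s), nchar(a)) >= 0.8
      }, logical(1)))
    }
    gen_class <- function(n, make_one, label) {
      out <- character(0)
      for (i in seq_len(n)) {
        ok <- FALSE
        for (try in 1:200) {
          s <- make_one()
          if (count_hits(s, V_MOTIF) == attr(make_one, "n_v_motif") &&
              count_hits(s, J_MOTIF) == attr(make_one, "n_j_motif") &&
              !too_similar(s, out)) {
            out <- c(out, s); ok <- TRUE; break
          }
        }
        if (!ok)
          stop("could not generate ", label,
               " fixture under the identity constraint", call. = FALSE)
      }
      out
    }
    make_v <- function() paste0(rand_dna(273), V_MOTIF, rand_dna(8))
    attr(make_v, "n_v_motif") <- 1L; attr(make_v, "n_j_motif") <- 0L
    make_j <- function() paste0(rand_dna(20), J_MOTIF, rand_dna(24))
    attr(make_j, "n_v_motif") <- 0L; attr(make_j, "n_j_motif") <- 1L
    make_d <- function() rand_dna(sample(10:35, 1))
    attr(make_d, "n_v_motif") <- 0L; attr(make_d, "n_j_motif") <- 0L

    v_seq <- gen_class(n_v, make_v, "V")
    d_seq <- gen_class(n_d, make_d, "D")
    j_seq <- gen_class(n_j, make_j, "J")

    v_names <- sprintf("IGHV1-S%d*01", seq_len(n_v))
    d_names <- sprintf("IGHD1-S%d*01", seq_len(n_d))
    j_names <- sprintf("IGHJ%d*01", seq_len(n_j))

    # optional sibling alleles of the first V gene (single substitution in
    # the framework, motif untouched)
    if (n_alleles_v > 1) {
      for (k in 2:n_alleles_v) {
        s <- v_seq[1]
        repeat {
          pos <- sample(1:200, 1)
          base <- substr(s, pos, pos)
          alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
          cand <- paste0(substr(s, 1, pos - 1), alt,
                         substr(s, pos + 1, nchar(s)))
          if (count_hits(cand, V_MOTIF) == 1 &&
              count_hits(cand, J_MOTIF) == 0) { s <- cand; break }
        }
        v_seq <- c(v_seq, s)
        v_names <- c(v_names, sprintf("IGHV1-S1*%02d", k))
      }
    }

    db <- tibble(
      name = c(v_names, d_names, j_names),
      gene = strip_allele(c(v_names, d_names, j_names)),
      segment = c(rep("V", length(v_names)), rep("D", n_d),
                  rep("J", n_j)),
      sequence = c(v_seq, d_seq, j_seq),
      motif_anchor = c(
        vapply(v_seq, motif_anchor_of, integer(1), motif = V_MOTIF,
               USE.NAMES = FALSE),
        rep(NA_integer_, n_d),
        vapply(j_seq, motif_anchor_of, integer(1), motif = J_MOTIF,
               USE.NAMES = FALSE)))
    db <- new_germline_db(db, source_label = sprintf(
      "synthetic fixture (n_v=%d, n_d=%d, n_j=%d, seed=%d)",
      n_v, n_d, n_j, seed))
    validate_germline_db(db)
    db
  })
}

#' @export
print.germline_db <- function(x, ...) {
  cat(sprintf("<germline_db: %d V, %d D, %d J>  %s\n",
              sum(x$segment == "V"), sum(x$segment == "D"),
              sum(x$segment == "J"), attr(x, "source_label")))
  NextMethod()
}
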