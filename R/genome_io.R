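#' Read a genome FASTA file
#'
#' Reads a (multi-record, wrapped or unwrapped) nucleotide FASTA file and
#' returns one row per contig. Sequences are upper-cased; IUPAC ambiguity
#' codes are preserved. Records violating the contig contract (duplicate
#' ids, characters outside the IUPAC nucleotide alphabet) are rejected with
#' an informative error.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `contig_id` (character) and `seq`
#'   (upper-case nucleotide string), one row per contig.
#' @examples
#' fa <- tempfile(fileext = ".fna")
#' writeLines(c(">c1", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file does not exist: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("Failed to parse FASTA '", path, "': ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0L) {
    abort(paste0("FASTA file is empty (no records): ", path))
  }
  # first whitespace-delimited token of the header is the contig id
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    abort(paste0("FASTA record with empty id in ", path))
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("Duplicate contig id(s) in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    abort(paste0("Zero-length contig sequence(s) in ", path, ": ",
                 paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  bad_re <- paste0("[^", paste(IUPAC_NT, collapse = ""), "]")
  hit <- regexpr(bad_re, seqs)
  if (any(hit > 0L)) {
    i <- which(hit > 0L)[1L]
    abort(sprintf(
      "Non-IUPAC nucleotide character '%s' in contig '%s' at position %d",
      substr(seqs[i], hit[i], hit[i]), ids[i], hit[i]))
  }
  tibble(contig_id = unname(ids), seq = unname(seqs))
}

#' Read PROKKA-style GFF3 feature annotations
#'
#' Parses a 9-column GFF3 file (1-based inclusive coordinates; a trailing
#' `##FASTA` section is tolerated and ignored). CDS, tRNA and rRNA rows keep
#' their type; every other row is retained with `ftype = "other"`. The
#' `product` and `locus_tag` attributes are extracted (`locus_tag` falls
#' back to `ID` when absent, as in PROKKA output).
#'
#' @param path Path to a GFF3 file.
#' @param contigs Contig tibble from [read_fasta()], used to validate that
#'   every feature lies on a known contig within its bounds.
#' @return A tibble with columns `contig_id`, `start`, `end`, `strand`,
#'   `ftype` (factor-free character: CDS/tRNA/rRNA/other), `product`,
#'   `locus_tag`.
#' @export
read_gff3 <- function(path, contigs) {
  if (!file.exists(path)) {
    abort(paste0("GFF3 file does not exist: ", path))
  }
  first <- readLines(path, n = 1L)
  if (!length(first) || !grepl("^##gff-version", first)) {
    abort(paste0("Missing ##gff-version header in ", path))
  }
  g <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "locus_tag", "product")))
  if (nrow(g) == 0L) {
    abort(paste0("GFF3 file has no feature rows: ", path))
  }
  ftype <- as.character(g$type)
  ftype[!ftype %in% c("CDS", "tRNA", "rRNA")] <- "other"
  feat <- tibble(
    contig_id = as.character(g$seqid),
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = as.character(g$strand),
    ftype = ftype,
    product = as.character(g$product %||% NA_character_),
    locus_tag = dplyr::coalesce(as.character(g$locus_tag %||% NA_character_),
                                as.character(g$ID %||% NA_character_))
  )
  feat$strand[!feat$strand %in% c("+", "-")] <- "+"
  validate_features(feat, contigs, path)
  feat
}

validate_features <- function(features, contigs, origin = "features") {
  clen <- setNames(nchar(contigs$seq), contigs$contig_id)
  unknown <- setdiff(unique(features$contig_id), names(clen))
  if (length(unknown)) {
    abort(paste0("Feature(s) on unknown contig(s) in ", origin, ": ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(features$start < 1L) || any(features$start > features$end)) {
    i <- which(features$start < 1L | features$start > features$end)[1L]
    abort(sprintf("Invalid coordinates for feature '%s' in %s: start=%d end=%d",
                  features$locus_tag[i], origin, features$start[i],
                  features$end[i]))
  }
  over <- features$end > clen[features$contig_id]
  if (any(over)) {
    i <- which(over)[1L]
    abort(sprintf(
      "Feature '%s' in %s ends at %d beyond contig '%s' length %d",
      features$locus_tag[i], origin, features$end[i], features$contig_id[i],
      clen[features$contig_id[i]]))
  }
  tags <- features$locus_tag[!is.na(features$locus_tag)]
  if (anyDuplicated(tags)) {
    abort(paste0("Duplicate locus_tag(s) in ", origin, ": ",
                 paste(unique(tags[duplicated(tags)]), collapse = ", ")))
  }
  invisible(features)
}

#' Assemble a genome record from sequence and annotation files
#'
#' @param fasta_path,gff_path Paths to the genome FASTA and GFF3 files.
#' @param genome_id Identifier for the genome; defaults to the FASTA file
#'   base name.
#' @param group_label Optional group label (e.g. `"PD"` or `"REF"`).
#' @return A `genome_record` object: a list with `genome_id`, `contigs`
#'   (tibble), `features` (tibble) and `group_label`.
#' @export
read_genome <- function(fasta_path, gff_path, genome_id = NULL,
                        group_label = NA_character_) {
  contigs <- read_fasta(fasta_path)
  features <- read_gff3(gff_path, contigs)
  genome_record(
    genome_id = genome_id %||% sub("\\.[^.]*$", "", basename(fasta_path)),
    contigs = contigs, features = features, group_label = group_label)
}

#' Construct a genome record from in-memory tables
#'
#' @param genome_id Genome identifier.
#' @param contigs Tibble with `contig_id`, `seq`.
#' @param features Tibble with `contig_id`, `start`, `end`, `strand`,
#'   `ftype`, `product`, `locus_tag`.
#' @param group_label Optional group label.
#' @return A `genome_record` object.
#' @export
genome_record <- function(genome_id, contigs, features,
                          group_label = NA_character_) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  contigs <- as_tibble(contigs)
  features <- as_tibble(features)
  if (anyDuplicated(contigs$contig_id)) {
    abort("Duplicate contig ids in genome record")
  }
  validate_features(features, contigs, genome_id)
  structure(
    list(genome_id = genome_id, contigs = contigs, features = features,
         group_label = group_label),
    class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s%s\n", x$genome_id,
              if (!is.na(x$group_label)) paste0(" [", x$group_label, "]")
              else ""))
  cat(sprintf("  %d contig(s), %s bp; %d feature(s) (%d CDS, %d tRNA, %d rRNA)\n",
              nrow(x$contigs), format(sum(nchar(x$contigs$seq)), big.mark = ","),
              nrow(x$features), sum(x$features$ftype == "CDS"),
              sum(x$features$ftype == "tRNA"), sum(x$features$ftype == "rRNA")))
  invisible(x)
}

#' Write a genome record to FASTA and GFF3 files
#'
#' Inverse of [read_genome()]: the written files read back to an identical
#' record (sequences and feature table round-trip exactly).
#'
#' @param genome A `genome_record`.
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, the genome record.
#' @export
write_genome <- function(genome, fasta_path, gff_path) {
  writeLines(paste0(">", genome$contigs$contig_id, "\n", genome$contigs$seq),
             fasta_path)
  f <- genome$features
  attrs <- paste0("ID=", f$locus_tag, ";locus_tag=", f$locus_tag,
                  ifelse(is.na(f$product), "", paste0(";product=", f$product)))
  rows <- paste(f$contig_id, "cryosig", f$ftype, f$start, f$end, ".",
                f$strand, ifelse(f$ftype == "CDS", "0", "."), attrs,
                sep = "\t")
  writeLines(c("##gff-version 3", rows), gff_path)
  invisible(genome)
}

#' Read a genome manifest table
#'
#' The manifest is a tab- or comma-separated table with columns `genome_id`,
#' `fasta_path`, `gff_path` and optionally `group_label`. Relative paths are
#' resolved against the manifest's own directory.
#'
#' @param path Path to the manifest file.
#' @return A tibble with the manifest columns, paths made absolute.
#' @export
read_genome_manifest <- function(path) {
  m <- read_table_auto(path)
  need <- c("genome_id", "fasta_path", "gff_path")
  if (!all(need %in% names(m))) {
    abort(paste0("Manifest must have columns ", paste(need, collapse = ", ")))
  }
  if (!"group_label" %in% names(m)) m$group_label <- NA_character_
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m |>
    mutate(fasta_path = fix(.data$fasta_path),
           gff_path = fix(.data$gff_path)) |>
    select(dplyr::all_of(c("genome_id", "fasta_path", "gff_path", "group_label")))
}

#' Load all genomes listed in a manifest
#'
#' @param manifest Manifest tibble from [read_genome_manifest()] (or a path).
#' @return A named list of `genome_record` objects.
#' @export
load_genomes <- function(manifest) {
  if (is.character(manifest)) manifest <- read_genome_manifest(manifest)
  recs <- purrr::pmap(manifest, function(genome_id, fasta_path, gff_path,
                                         group_label, ...) {
    read_genome(fasta_path, gff_path, genome_id, group_label)
  })
  setNames(recs, manifest$genome_id)
}

# delimiter-sniffing reader for small tabular inputs (TSV or CSV)
read_table_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("File does not exist: ", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Extract the nucleotide sequence of genome features
#'
#' Slices feature intervals (1-based inclusive) out of their contigs;
#' minus-strand features are returned reverse-complemented.
#'
#' @param genome A `genome_record`.
#' @param features Tibble of features to extract; defaults to all features
#'   of the genome.
#' @return A character vector of sequences named by `locus_tag`.
#' @export
extract_feature_seq <- function(genome, features = genome$features) {
  if (nrow(features) == 0L) return(setNames(character(), character()))
  validate_features(features, genome$contigs, genome$genome_id)
  seqs <- setNames(genome$contigs$seq, genome$contigs$contig_id)
  out <- substr(seqs[features$contig_id], features$start, features$end)
  minus <- features$strand == "-"
  if (any(minus)) {
    out[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out[minus])))
  }
  setNames(unname(out), features$locus_tag)
}

#' Translate coding sequences
#'
#' Translates nucleotide CDS with a fixed genetic code (default: table 11,
#' bacterial/archaeal), applying the code table uniformly (alternative
#' initiator codons are not promoted to Met). A trailing stop codon is
#' removed from the protein.
#' Sequences whose length is not a multiple of 3 are handled by the partial
#' policy: dropped with a warning (default) or rejected (`partial =
#' "strict"`). Sequences translating with an internal stop are flagged as
#' pseudogenes and excluded from downstream composition statistics.
#'
#' @param seqs Character vector of CDS nucleotide sequences (optionally
#'   named by locus tag).
#' @param code Genetic code table identifier passed to
#'   [Biostrings::getGeneticCode()]; default `"11"`.
#' @param partial Partial-CDS policy: `"drop"` (default) or `"strict"`.
#' @return A tibble with columns `locus_tag`, `protein` (NA when not
#'   retained) and `status` (`"ok"`, `"partial"` or `"pseudogene"`).
#' @examples
#' translate_cds(c(g1 = "ATGAAATAA"))
#' @export
translate_cds <- function(seqs, code = "11", partial = c("drop", "strict")) {
  partial <- match.arg(partial)
  n <- length(seqs)
  tags <- names(seqs) %||% paste0("cds", seq_len(n))
  status <- rep("ok", n)
  protein <- rep(NA_character_, n)
  bad_len <- (nchar(seqs) %% 3L) != 0L
  if (any(bad_len)) {
    if (partial == "strict") {
      abort(sprintf("CDS length not divisible by 3: %s",
                    paste(head(tags[bad_len], 5L), collapse = ", ")))
    }
    warn(sprintf("Dropping %d partial CDS (length not divisible by 3)",
                 sum(bad_len)))
    status[bad_len] <- "partial"
  }
  keep <- !bad_len
  if (any(keep)) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(seqs[keep]),
      genetic.code = Biostrings::getGeneticCode(code),
      no.init.codon = TRUE, if.fuzzy.codon = "solve"))
    # trailing stop is expected and stripped; internal stops mark pseudogenes
    aa_trim <- sub("\\*$", "", aa)
    pseudo <- grepl("\\*", aa_trim)
    st <- status[keep]
    st[pseudo] <- "pseudogene"
    status[keep] <- st
    pr <- ifelse(pseudo, NA_character_, aa_trim)
    protein[keep] <- pr
  }
  tibble(locus_tag = tags, protein = protein, status = status)
}

#' Translate all annotated CDS of a genome
#'
#' @inheritParams translate_cds
#' @param genome A `genome_record`.
#' @return Tibble as for [translate_cds()], restricted to CDS features.
#' @export
genome_proteins <- function(genome, code = "11", partial = "drop") {
  cds <- genome$features |> filter(.data$ftype == "CDS")
  translate_cds(extract_feature_seq(genome, cds), code = code,
                partial = partial)
}
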