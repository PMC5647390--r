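# Assembly, metadata and annotation I/O plus run configuration.

#' @importFrom Biostrings DNAStringSet readDNAStringSet reverseComplement
#'   AAStringSet translate getGeneticCode
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames strand start end
#' @importFrom IRanges IRanges
NULL

#' Read a genome assembly
#'
#' Reads a (multi-contig) assembly from FASTA or a GenBank flat file into
#' a `DNAStringSet` whose element metadata carries the strain, species and
#' topology. Sequences are upper-cased; the alphabet is restricted to
#' A/C/G/T/N -- ambiguity codes beyond N are rejected, as are empty
#' records and duplicate contig ids.
#'
#' @param path FASTA (default) or GenBank flat file.
#' @param strain_id strain identifier attached to every contig.
#' @param species species name (optional).
#' @param format `"fasta"` or `"genbank"`; guessed from the extension.
#' @param topology `"linear"` or `"circular"`, recycled over contigs.
#' @return A `DNAStringSet` named by contig id with `mcols()` columns
#'   `strain_id`, `species`, `topology`.
#' @export
readAssembly <- function(path, strain_id, species = "",
                         format = c("auto", "fasta", "genbank"),
                         topology = "linear") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read assembly file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(gb|gbk|gbff|genbank)$", path,
                        ignore.case = TRUE)) "genbank" else "fasta"
  if (format == "fasta") {
    raw <- readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(raw))
    seqs <- toupper(as.character(raw))
  } else {
    gb <- .readGenbankSeqs(path)
    ids <- names(gb)
    seqs <- toupper(gb)
  }
  makeContigSet(seqs, contig_ids = ids, strain_id = strain_id,
                species = species, topology = topology)
}

#' Assemble a contig set from in-memory sequences
#'
#' @param seqs character vector of DNA sequences.
#' @param contig_ids contig identifiers (unique within the strain).
#' @inheritParams readAssembly
#' @return A validated `DNAStringSet` as in [readAssembly()].
#' @export
makeContigSet <- function(seqs, contig_ids, strain_id, species = "",
                          topology = "linear") {
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) {
    bad <- contig_ids[!nzchar(seqs)]
    stop("empty sequence record: ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(contig_ids))
    stop("duplicate contig id within strain: ",
         paste(unique(contig_ids[duplicated(contig_ids)]), collapse = ", "))
  offending <- grepl("[^ACGTN]", seqs)
  if (any(offending))
    stop("characters outside {A,C,G,T,N} in record(s): ",
         paste(contig_ids[offending], collapse = ", "))
  if (!all(topology %in% c("linear", "circular")))
    stop("topology must be 'linear' or 'circular'")
  x <- DNAStringSet(seqs)
  names(x) <- contig_ids
  mcols(x) <- DataFrame(strain_id = strain_id, species = species,
                        topology = rep(topology, length.out = length(x)))
  x
}

## Minimal GenBank flat-file sequence reader: LOCUS name + ORIGIN block.
.readGenbankSeqs <- function(path) {
  lines <- readLines(path)
  loci <- grep("^LOCUS", lines)
  if (length(loci) == 0L) stop("no LOCUS records found in ", path)
  ends <- grep("^//", lines)
  if (length(ends) < length(loci)) ends <- c(ends, length(lines))
  out <- character(0)
  for (k in seq_along(loci)) {
    block <- lines[loci[k]:ends[k]]
    id <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
    ori <- grep("^ORIGIN", block)
    if (length(ori) == 0L) stop("GenBank record without ORIGIN: ", id)
    seq_lines <- block[(ori[1] + 1L):(length(block) - 1L)]
    seq <- gsub("[0-9 /]", "", paste(seq_lines, collapse = ""))
    out[id] <- seq
  }
  out
}

#' Read strain metadata
#'
#' Reads a tab-separated metadata table (columns `strain_id`, `species`,
#' `host`, `geo_location`, `collection_date`, emulating BioSample
#' fields). Absent values are recorded as `NA`, never as empty strings.
#'
#' @param path TSV file with a header row.
#' @return A `data.frame`, one row per strain.
#' @export
readMetadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character",
                          na.strings = c("", "NA"))
  need <- c("strain_id", "species")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("metadata missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (opt in c("host", "geo_location", "collection_date"))
    if (!opt %in% names(df)) df[[opt]] <- NA_character_
  if (anyDuplicated(df$strain_id))
    stop("duplicate strain_id in metadata: ",
         paste(unique(df$strain_id[duplicated(df$strain_id)]),
               collapse = ", "))
  df
}

#' @rdname readMetadata
#' @param metadata a metadata `data.frame`.
#' @export
writeMetadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write accepted TA loci as GFF3
#'
#' Emits one `operon` parent feature per locus plus one `gene` child per
#' ORF, with 1-based inclusive coordinates (the native convention of both
#' the package's ranges and GFF3). The file round-trips through a GFF3
#' parser.
#'
#' @param loci a locus table as returned by the search strategies (see
#'   [cascadeSearch()]).
#' @param path output file.
#' @param contigs optional `DNAStringSet`; when supplied, loci referring
#'   to unknown contigs raise a validation error.
#' @return Invisibly, `path`.
#' @export
writeLociGff <- function(loci, path, contigs = NULL) {
  if (!is.null(contigs) && nrow(loci) > 0) {
    unknown <- setdiff(loci$contig_id, names(contigs))
    if (length(unknown))
      stop("locus references unknown contig(s): ",
           paste(unknown, collapse = ", "))
  }
  if (nrow(loci) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  op <- GRanges(loci$contig_id,
                IRanges(pmin(loci$at_start, loci$tox_start),
                        pmax(loci$at_end, loci$tox_end)),
                strand = loci$strand)
  mcols(op) <- DataFrame(type = "operon", ID = loci$locus_id,
                         Parent = NA_character_,
                         locus_role = NA_character_)
  kid <- function(role, s, e) {
    g <- GRanges(loci$contig_id, IRanges(s, e), strand = loci$strand)
    mcols(g) <- DataFrame(type = "gene",
                          ID = paste0(loci$locus_id, ".", role),
                          Parent = loci$locus_id, locus_role = role)
    g
  }
  gr <- c(op, kid("antitoxin", loci$at_start, loci$at_end),
          kid("toxin", loci$tox_start, loci$tox_end))
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Any subset of [PipelineConfig-class] fields may appear in the file;
#' unnamed fields keep their defaults.
#'
#' @param path YAML file.
#' @return A [PipelineConfig-class].
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}
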