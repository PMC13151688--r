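# Genomic I/O: genome/annotation ingestion, strand-aware promoter windows,
# redundancy collapse of proteins, domain-hit tables, chromosome summaries.
#
# Coordinate convention: GFF3 is 1-based inclusive on disk and converted on
# read; all internal intervals are 0-based half-open, and BED is written
# 0-based half-open.

#' Read a genome FASTA into a named character vector
#'
#' Sequences are uppercased; the alphabet is restricted to A, C, G, T, N.
#'
#' @param path Path to a (possibly wrapped) FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(dss))
  # drop FASTA description text after the first whitespace
  names(seqs) <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence ids in ", path, call. = FALSE)
  }
  seqs
}

#' Write sequences as wrapped FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Parse gene models from a GFF3 file
#'
#' Only rows of feature type \code{gene} are consumed. The gene identifier is
#' taken from the \code{ID} attribute, stripping any \code{gene:} prefix.
#'
#' @param gff3 Path to a GFF3 file, or a character vector of GFF3 lines.
#' @return A data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive, as annotated) and
#'   \code{strand}.
#' @export
parse_gff3_genes <- function(gff3) {
  path <- gff3
  if (length(gff3) > 1L || !file.exists(gff3[1])) {
    path <- tempfile(fileext = ".gff3")
    on.exit(unlink(path), add = TRUE)
    writeLines(gff3, path)
  }
  tab <- rtracklayer::readGFF(path, columns = c("seqid", "type", "start", "end", "strand"),
                              tags = "ID")
  tab <- as.data.frame(tab)
  genes <- tab[as.character(tab$type) == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  ids <- as.character(genes$ID)
  if (anyNA(ids) || any(ids == "")) {
    bad <- which(is.na(ids) | ids == "")[1]
    stop(sprintf("gene row %d (%s:%d-%d) lacks an ID attribute",
                 bad, genes$seqid[bad], genes$start[bad], genes$end[bad]),
         call. = FALSE)
  }
  ids <- sub("^gene:", "", ids)
  if (any(genes$start > genes$end)) {
    bad <- which(genes$start > genes$end)[1]
    stop(sprintf("gene '%s' has start > end (%d > %d)",
                 ids[bad], genes$start[bad], genes$end[bad]), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  data.frame(gene_id = ids,
             chrom = as.character(genes$seqid),
             start = as.integer(genes$start),
             end = as.integer(genes$end),
             strand = as.character(genes$strand),
             stringsAsFactors = FALSE)
}

#' Extract fixed-length upstream promoter windows
#'
#' For a + strand gene the window covers the \code{upstream_len} bases
#' immediately 5' of the gene start (excluding the gene's first base); for a
#' - strand gene, the \code{upstream_len} bases immediately 3' of the gene
#' end in genome coordinates, reverse-complemented so stored sequences read
#' 5' to 3' relative to the gene. Windows are clipped at chromosome
#' boundaries; zero-length windows are dropped with a warning. Overlap with
#' neighboring genes is deliberately not trimmed, and 'N' bases are kept.
#'
#' @param genes data.frame as returned by [parse_gff3_genes()].
#' @param genome Named character vector of chromosome sequences.
#' @param upstream_len Window length in bp (default 2000).
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start0}, \code{end0} (0-based half-open), \code{strand},
#'   \code{sequence}.
#' @export
extract_promoters <- function(genes, genome, upstream_len = 2000L) {
  stopifnot(upstream_len >= 1L)
  missing_chrom <- !(genes$chrom %in% names(genome))
  if (any(missing_chrom)) {
    stop(sprintf("gene '%s' refers to unknown chromosome '%s'",
                 genes$gene_id[which(missing_chrom)[1]],
                 genes$chrom[which(missing_chrom)[1]]), call. = FALSE)
  }
  chrlen <- nchar(genome)[genes$chrom]
  plus <- genes$strand == "+"
  start0 <- ifelse(plus, pmax(0L, genes$start - 1L - upstream_len), genes$end)
  end0 <- ifelse(plus, genes$start - 1L, pmin(chrlen, genes$end + upstream_len))
  keep <- end0 > start0
  if (any(!keep)) {
    warning(sprintf("dropping %d zero-length promoter(s): %s",
                    sum(!keep), paste(genes$gene_id[!keep], collapse = ", ")),
            call. = FALSE)
  }
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start0 = as.integer(start0), end0 = as.integer(end0),
                    strand = genes$strand, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  seqs <- substr(genome[out$chrom], out$start0 + 1L, out$end0)
  minus <- out$strand == "-"
  if (any(minus)) seqs[minus] <- reverse_complement(seqs[minus])
  out$sequence <- unname(seqs)
  rownames(out) <- NULL
  out
}

#' Write promoter intervals as BED6
#'
#' Columns: chrom, start0, end0, gene_id, score ("."), strand.
#'
#' @param promoters data.frame from [extract_promoters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters_bed <- function(promoters, path) {
  bed <- data.frame(promoters$chrom, promoters$start0, promoters$end0,
                    promoters$gene_id, ".", promoters$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Re-extract promoter sequences from BED + FASTA
#'
#' Strand-aware counterpart of `bedtools getfasta -s`: - strand intervals are
#' reverse-complemented. Used for round-trip validation of the coordinate
#' conventions.
#'
#' @param bed_path BED6 file written by [write_promoters_bed()].
#' @param fasta_path Genome FASTA.
#' @return Named character vector of sequences (names = BED name column).
#' @export
extract_bed_sequences <- function(bed_path, fasta_path) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start0", "end0", "name",
                                         "score", "strand"),
                           stringsAsFactors = FALSE)
  genome <- read_genome_fasta(fasta_path)
  seqs <- substr(genome[bed$chrom], bed$start0 + 1L, bed$end0)
  minus <- bed$strand == "-"
  if (any(minus)) seqs[minus] <- reverse_complement(seqs[minus])
  names(seqs) <- bed$name
  seqs
}

#' Collapse proteins that are 100% identical
#'
#' Records with identical sequences (after uppercasing and stripping one
#' trailing stop mark '*') share one representative, the first by input
#' order. This is exact full-length identity: substring containment at
#' shorter lengths does not cluster.
#'
#' @param records Named character vector of protein sequences.
#' @return list with \code{representatives} (named character vector,
#'   input order preserved) and \code{cluster_map} (named character vector
#'   mapping each non-representative member id to its representative id).
#' @export
collapse_identical_proteins <- function(records) {
  if (length(records) == 0L) {
    return(list(representatives = stats::setNames(character(), character()),
                cluster_map = stats::setNames(character(), character())))
  }
  stopifnot(!is.null(names(records)))
  canon <- sub("\\*$", "", toupper(records))
  if (any(canon == "")) {
    stop("empty protein sequence after stripping stop mark: ",
         names(records)[canon == ""][1], call. = FALSE)
  }
  first <- !duplicated(canon)
  rep_of <- names(records)[first][match(canon, canon[first])]
  members <- !first
  list(representatives = records[first],
       cluster_map = stats::setNames(rep_of[members], names(records)[members]))
}

#' Read a HMMER3 per-domain table
#'
#' Whitespace-delimited domain tabular layout ('--domtblout'); comment lines
#' start with '#'. The independent per-domain E-value (column 13) is
#' filtered against \code{evalue_max}; multiple domains per protein are kept
#' as separate hits.
#'
#' @param path Path to the table (or a character vector of its lines).
#' @param evalue_max Retain hits with E-value <= this bound.
#' @return data.frame with columns \code{protein_id},
#'   \code{domain_accession}, \code{env_start}, \code{env_end}, \code{evalue}.
#' @export
read_domain_hits <- function(path, evalue_max) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  out <- data.frame(protein_id = character(), domain_accession = character(),
                    env_start = integer(), env_end = integer(),
                    evalue = numeric(), stringsAsFactors = FALSE)
  if (length(rows) == 0L) return(out)
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields < 21L)) {
    stop(sprintf("line %d: expected >= 21 whitespace-delimited fields, got %d",
                 rows[which(n_fields < 21L)[1]], min(n_fields)), call. = FALSE)
  }
  get <- function(k) vapply(fields, `[[`, "", k)
  evalue <- suppressWarnings(as.numeric(get(13)))
  env_start <- suppressWarnings(as.integer(get(20)))
  env_end <- suppressWarnings(as.integer(get(21)))
  bad <- is.na(evalue) | is.na(env_start) | is.na(env_end)
  if (any(bad)) {
    stop(sprintf("line %d: unparseable numeric field", rows[which(bad)[1]]),
         call. = FALSE)
  }
  out <- data.frame(protein_id = get(1),
                    domain_accession = get(5),
                    env_start = env_start, env_end = env_end,
                    evalue = evalue, stringsAsFactors = FALSE)
  if (any(out$env_start > out$env_end)) {
    stop(sprintf("line %d: envelope start exceeds end",
                 rows[which(out$env_start > out$env_end)[1]]), call. = FALSE)
  }
  out[out$evalue <= evalue_max, , drop = FALSE]
}

#' Count genes per chromosome
#'
#' @param genes data.frame as returned by [parse_gff3_genes()].
#' @return Named integer vector, chromosome id -> gene count.
#' @export
chromosome_counts <- function(genes) {
  if (nrow(genes) == 0L) return(stats::setNames(integer(), character()))
  tab <- table(genes$chrom)
  stats::setNames(as.integer(tab), names(tab))
}
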