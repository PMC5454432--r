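# Readers and writers for every external format the pipeline touches.
# One conversion point: GFF's 1-based inclusive coordinates become 0-based
# half-open on the way in and are converted back on the way out.

#' Construct a genome record
#'
#' The basic container of the package: one named nucleotide sequence with an
#' optional geographic location and a feature table.
#'
#' @param id unique sequence identifier
#' @param sequence nucleotide string over A/C/G/T/N (uppercased on input)
#' @param location free-text geographic label (e.g. "Nymph Lake"), or NA
#' @param features data.frame with columns feature_id, start, end (0-based
#'   half-open), strand ("+"/"-"), kind ("CDS", "repeat", "spacer", "other")
#' @return object of class `genome_record`
#' @export
genome_record <- function(id, sequence, location = NA_character_,
                          features = empty_features()) {
  sequence <- chartr("U", "T", toupper(sequence))
  if (!nzchar(sequence)) stop("genome '", id, "': empty sequence")
  stopifnot(is.data.frame(features))
  validate_features(features, nchar(sequence), id)
  structure(list(id = id, sequence = sequence, location = location,
                 features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, G+C %.1f%%, %d features%s\n",
              x$id, nchar(x$sequence), 100 * gc_content(x$sequence),
              nrow(x$features),
              if (is.na(x$location)) "" else paste0(" [", x$location, "]")))
  invisible(x)
}

#' @rdname genome_record
#' @export
empty_features <- function() {
  data.frame(feature_id = character(), start = integer(), end = integer(),
             strand = character(), kind = character(),
             stringsAsFactors = FALSE)
}

validate_features <- function(features, genome_len, id) {
  if (!nrow(features)) return(invisible(TRUE))
  req <- c("feature_id", "start", "end", "strand", "kind")
  miss <- setdiff(req, names(features))
  if (length(miss)) stop("feature table lacks columns: ",
                         paste(miss, collapse = ", "))
  bad <- features$end <= features$start
  if (any(bad)) stop("genome '", id, "': feature '",
                     features$feature_id[which(bad)[1]], "' has end <= start")
  oob <- features$start < 0L | features$end > genome_len
  if (any(oob)) stop("genome '", id, "': feature '",
                     features$feature_id[which(oob)[1]],
                     "' lies outside [0, ", genome_len, ")")
  invisible(TRUE)
}

#' Read genomes from a FASTA file
#'
#' Sequences are uppercased and U is mapped to T. Record order is preserved.
#'
#' @param path FASTA file
#' @param sample_sheet optional data.frame from [read_sample_sheet()] used to
#'   attach geographic locations by id
#' @return named list of [genome_record()] objects
#' @export
read_fasta <- function(path, sample_sheet = NULL) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1])
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    loc <- NA_character_
    if (!is.null(sample_sheet)) {
      j <- match(ids[i], sample_sheet$id)
      if (!is.na(j)) loc <- sample_sheet$location[j]
    }
    out[[i]] <- genome_record(ids[i], as.character(set[[i]]), location = loc)
  }
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#'
#' @param genomes list of [genome_record()]
#' @param path output file
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    writeLines(paste0(">", g$id), con)
    s <- g$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

GFF_KIND_MAP <- c(CDS = "CDS", repeat_region = "repeat",
                  direct_repeat = "repeat", spacer = "spacer")

#' Attach GFF3 features to genomes
#'
#' Coordinates are converted from GFF's 1-based inclusive convention to the
#' internal 0-based half-open one. Features referencing unknown sequence ids,
#' inverted intervals or out-of-bounds intervals are rejected.
#'
#' @param path GFF3 file
#' @param genomes named list of [genome_record()]
#' @return the genomes, with `features` tables filled
#' @export
read_gff <- function(path, genomes) {
  gff <- as.data.frame(rtracklayer::readGFF(path))
  if (!nrow(gff)) return(genomes)
  unknown <- setdiff(unique(as.character(gff$seqid)), names(genomes))
  if (length(unknown)) stop("GFF references unknown sequence id: ", unknown[1])
  if (any(gff$end < gff$start)) {
    i <- which(gff$end < gff$start)[1]
    stop("GFF feature with end < start at ", gff$seqid[i], ":", gff$start[i])
  }
  ids <- as.character(gff$ID)
  if (is.null(gff$ID)) ids <- rep(NA_character_, nrow(gff))
  ids[is.na(ids) | !nzchar(ids)] <-
    paste0("feat", seq_len(sum(is.na(ids) | !nzchar(ids))))
  kind <- unname(GFF_KIND_MAP[as.character(gff$type)])
  kind[is.na(kind)] <- "other"
  for (i in seq_len(nrow(gff))) {
    sid <- as.character(gff$seqid[i])
    g <- genomes[[sid]]
    feat <- data.frame(feature_id = ids[i],
                       start = as.integer(gff$start[i]) - 1L,
                       end = as.integer(gff$end[i]),
                       strand = as.character(gff$strand[i]),
                       kind = kind[i], stringsAsFactors = FALSE)
    validate_features(feat, nchar(g$sequence), sid)
    g$features <- rbind(g$features, feat)
    genomes[[sid]] <- g
  }
  genomes
}

#' Write genome features as GFF3
#'
#' Internal 0-based half-open coordinates are emitted 1-based inclusive.
#'
#' @param genomes named list of [genome_record()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gff <- function(genomes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  rev_kind <- c(CDS = "CDS", "repeat" = "repeat_region", spacer = "spacer",
                other = "misc_feature")
  for (g in genomes) {
    f <- g$features
    if (!nrow(f)) next
    writeLines(sprintf("%s\tsirvpop\t%s\t%d\t%d\t.\t%s\t%s\tID=%s",
                       g$id, rev_kind[f$kind], f$start + 1L, f$end,
                       f$strand, ifelse(f$kind == "CDS", "0", "."),
                       f$feature_id), con)
  }
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated table with columns `id`, `location`, `region` and optional
#' `spring`/`type`; locations travel as metadata rather than being parsed out
#' of FASTA headers.
#'
#' @param path TSV file
#' @return data.frame
#' @export
read_sample_sheet <- function(path) {
  ss <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("id", "location", "region")
  miss <- setdiff(req, names(ss))
  if (length(miss)) stop("sample sheet lacks columns: ",
                         paste(miss, collapse = ", "))
  ss
}

#' Read an infection-outcome matrix
#'
#' Long-format TSV with columns `host_id`, `virus_id`, `titer` (one of
#' high/medium/low) and `clearing` (replicates with a zone of clearing, 0-3).
#'
#' @param path TSV file
#' @return data.frame of class `infection_matrix`
#' @export
read_infection_matrix <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("host_id", "virus_id", "titer", "clearing")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("infection matrix lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!all(x$titer %in% c("high", "medium", "low")))
    stop("titer must be one of high/medium/low")
  if (!all(x$clearing %in% 0:3))
    stop("clearing counts must be integers in 0..3")
  x$titer <- factor(x$titer, levels = c("high", "medium", "low"))
  class(x) <- c("infection_matrix", "data.frame")
  x
}

format_num <- function(x, digits = 6L) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

#' Write result tables and a run manifest
#'
#' Every data.frame in `results` is written as a TSV with deterministic
#' column order and row sort (all columns, left to right); numeric columns
#' are fixed to 6 significant digits. A `manifest.json` records the
#' configuration, the seed and md5 checksums of the emitted files, so a run
#' can be reproduced exactly.
#'
#' @param results named list of data.frames
#' @param out_dir output directory (created if needed)
#' @param config list serialized into the manifest
#' @param seed integer seed recorded in the manifest
#' @return paths of the written files, invisibly
#' @export
write_tables <- function(results, out_dir, config = list(), seed = NA) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  stopifnot(is.list(results), !is.null(names(results)))
  paths <- character(0)
  for (nm in names(results)) {
    df <- results[[nm]]
    stopifnot(is.data.frame(df))
    if (nrow(df)) {
      ord <- do.call(order, c(unname(as.list(df)), list(method = "radix")))
      df <- df[ord, , drop = FALSE]
    }
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    for (cl in names(df)[num]) df[[cl]] <- format_num(df[[cl]])
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "sirvpop",
    version = as.character(utils::packageVersion("sirvpop")),
    seed = seed,
    config = config,
    files = as.list(tools::md5sum(paths))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(c(paths, mp))
}
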