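# Readers and writers for the formats the pipeline touches. Coordinates
# are 0-based half-open everywhere inside the package and converted to
# 1-based inclusive only at the GFF3/BED boundary.

#' Read a (multi-)FASTA file
#'
#' @param path file path.
#' @return named character vector of uppercase sequences (U converted
#'   to T).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(gsub("U", "T", toupper(as.character(x)), fixed = TRUE), names(x))
}

#' Write sequences to FASTA, wrapped at 60 columns
#'
#' @param seqs named character vector.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(as.list(seqs)))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write hallmark hits as TSV
#'
#' Columns: contig, start, end (0-based half-open), strand, identity,
#' score, query_id, n_aligned.
#'
#' @param hits tibble from [scan_genome()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    contig = "c", start = "i", end = "i", strand = "c", identity = "d",
    score = "i", query_id = "c", n_aligned = "i"))
}

#' Write hits or annotations as BED6
#'
#' @param x tibble with `contig`, `start`, `end`, `strand` and either
#'   `score` (hits) or `element_class` (annotations).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path) {
  name <- if ("element_class" %in% names(x)) x$element_class
  else if ("query_id" %in% names(x)) x$query_id else "."
  score <- if ("score" %in% names(x)) x$score else 0L
  bed <- tibble(chrom = x$contig, start = x$start, end = x$end,
                name = name, score = score, strand = x$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

annotations_to_granges <- function(annotations) {
  rows <- list()
  add <- function(contig, start0, end0, strand, type, id, parent = NA,
                  class = NA, confidence = NA) {
    rows[[length(rows) + 1L]] <<- tibble(
      contig = contig, start = start0 + 1L, end = end0, strand = strand,
      type = type, ID = id, Parent = parent, element_class = class,
      confidence = confidence)
  }
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    add(a$contig, a$start, a$end, a$strand, "dispersed_repeat", a$locus_id,
        class = a$element_class, confidence = a$confidence)
    hm <- a$hallmarks[[1]]
    for (k in seq_len(nrow(hm)))
      add(hm$contig[k], hm$start[k], hm$end[k], hm$strand[k],
          "hallmark", paste0(a$locus_id, ".sig", k), parent = a$locus_id)
    if (!is.na(a$polya_start))
      add(a$contig, a$polya_start, a$polya_end, a$strand, "polyA_site",
          paste0(a$locus_id, ".polyA"), parent = a$locus_id)
    tsd <- a$tsd[[1]]
    if (nrow(tsd)) {
      add(a$contig, tsd$left_start, tsd$left_start + tsd$length, a$strand,
          "TSD", paste0(a$locus_id, ".tsdL"), parent = a$locus_id)
      add(a$contig, tsd$right_start, tsd$right_start + tsd$length, a$strand,
          "TSD", paste0(a$locus_id, ".tsdR"), parent = a$locus_id)
    }
  }
  df <- dplyr::bind_rows(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- df$Parent
  S4Vectors::mcols(gr)$element_class <- df$element_class
  S4Vectors::mcols(gr)$confidence <- df$confidence
  gr
}

#' Write element annotations as GFF3
#'
#' Parent features of type `dispersed_repeat` carry `element_class` and
#' `confidence` attributes; child features describe each hallmark
#' signature, the poly-A site and the two TSD copies. Coordinates are
#' 1-based inclusive per the GFF3 convention.
#'
#' @param annotations output of [annotate_genome()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_annotations_gff3 <- function(annotations, path) {
  gr <- annotations_to_granges(annotations)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read back annotation parents from a GFF3 file
#'
#' @param path file path.
#' @return tibble of parent features with 0-based half-open `start`/`end`,
#'   `strand`, `element_class`, `confidence`.
#' @export
read_annotations_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[S4Vectors::mcols(gr)$type == "dispersed_repeat"]
  tibble(locus_id = as.character(S4Vectors::mcols(gr)$ID),
         contig = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)),
         element_class = as.character(S4Vectors::mcols(gr)$element_class),
         confidence = as.character(S4Vectors::mcols(gr)$confidence))
}

#' Read / write cleavage time-courses
#'
#' The TSV dialect has columns `replicate_id`, `mg_mM`, `time_min`,
#' `fc_pct` (cleaved fraction, percent).
#'
#' @param path file path.
#' @return tibble.
#' @export
read_timecourse_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    replicate_id = "c", mg_mM = "d", time_min = "d", fc_pct = "d"))
}

#' @rdname read_timecourse_tsv
#' @param tc time-course tibble.
#' @export
write_timecourse_tsv <- function(tc, path) {
  readr::write_tsv(tc, path)
  invisible(path)
}

#' Write fitted kinetics parameters as a wide TSV
#'
#' One row per ribozyme/replicate, with the two-phase R^2, the plateau and
#' the hyperbolic R^2 spread over the assayed Mg concentrations, mirroring
#' the usual kinetics-table layout.
#'
#' @param fits output of [fit_kinetics_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fit_tsv <- function(fits, path) {
  wide <- fits |>
    dplyr::select("replicate_id", "mg_mM", "r2_two_phase", "plateau_pct",
                  "r2_hyperbolic") |>
    tidyr::pivot_wider(
      names_from = "mg_mM",
      values_from = c("r2_two_phase", "plateau_pct", "r2_hyperbolic"),
      names_glue = "{.value}_mg{mg_mM}")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Write fold assignments as layered dot-bracket text
#'
#' Each record is three lines: a `>` header, the sequence, and the
#' dot-bracket string using `()` for the nested layer (P1, P2, P4), `[]`
#' for P3 and `{}` for P1.1.
#'
#' @param folds a named list of `fold_assignment` objects.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(folds, path) {
  if (is.null(names(folds)))
    names(folds) <- paste0("candidate", seq_along(folds))
  lines <- unlist(purrr::imap(folds, function(f, nm) {
    c(paste0(">", nm), f$seq, f$dotbracket)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Load a pipeline configuration from YAML
#'
#' The file may contain the top-level keys `scan`, `descriptor`, `polya`,
#' `tsd`, `tandem_gap`, `max_rounds`, `long_ref` and `rng_seed`; unknown
#' keys (at top level or within a section) are rejected, and all values
#' are validated by the respective constructors.
#'
#' @param path YAML file path.
#' @return an [annotate_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("scan", "descriptor", "polya", "tsd", "tandem_gap",
             "max_rounds", "long_ref", "rng_seed")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    abort(paste0("unknown configuration key(s): ", paste(extra, collapse = ", ")))
  call_checked <- function(fn, args, section) {
    extra <- setdiff(names(args), names(formals(fn)))
    if (length(extra))
      abort(paste0("unknown key(s) in ", section, ": ",
                   paste(extra, collapse = ", ")))
    do.call(fn, args)
  }
  annotate_config(
    scan = call_checked(scan_params, raw$scan %||% list(), "scan"),
    descriptor = call_checked(ribozyme_descriptor, raw$descriptor %||% list(),
                              "descriptor"),
    polya = call_checked(polya_config, raw$polya %||% list(), "polya"),
    tsd = call_checked(tsd_config, raw$tsd %||% list(), "tsd"),
    tandem_gap = raw$tandem_gap %||% 200L,
    max_rounds = raw$max_rounds %||% 4L,
    long_ref = raw$long_ref,
    rng_seed = raw$rng_seed %||% 1L)
}

#' Write a run manifest recording every parameter
#'
#' @param config an [annotate_config()].
#' @param path JSON file path.
#' @param extra optional named list of additional entries (seeds, input
#'   files, package version).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, extra = list()) {
  payload <- c(list(package = "siderscan",
                    version = as.character(utils::packageVersion("siderscan")),
                    config = unclass(config)), extra)
  payload$config$descriptor <- unclass(payload$config$descriptor)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
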