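#' Read exon annotation from GFF3 or BED12
#'
#' Imports transcript exon structures and normalizes them to the package's
#' internal convention: 0-based half-open intervals, one row per exon,
#' sorted by genomic start within each transcript. GFF3 `exon` features are
#' attached to their parent transcript (1-based closed coordinates are
#' converted on read); BED12 blocks become exons. Exons that overlap within
#' one transcript violate the annotation invariant and raise an error; exons
#' without a resolvable parent transcript are skipped with a warning count.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` (BED12) file.
#' @return A tibble with columns `transcript_id`, `gene_id`, `strand`,
#'   `exon_start`, `exon_end` (0-based half-open) and `exon_rank` (1 = most
#'   5' exon on the genome's forward coordinate order). The attribute
#'   `"skipped_orphans"` counts exon features without a parent transcript.
#' @export
read_exon_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  is_bed <- grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)
  skipped <- 0L
  if (is_bed) {
    gr <- rtracklayer::import(path, format = "BED")
    blocks <- gr$blocks
    if (is.null(blocks)) {
      # BED6: one exon per record
      exons <- tibble(
        transcript_id = as.character(gr$name),
        gene_id = as.character(gr$name),
        strand = as.character(BiocGenerics::strand(gr)),
        exon_start = BiocGenerics::start(gr) - 1L,
        exon_end = BiocGenerics::end(gr)
      )
    } else {
      exons <- purrr::map_dfr(seq_along(gr), function(i) {
        b <- blocks[[i]]
        tibble(
          transcript_id = as.character(gr$name[i]),
          gene_id = as.character(gr$name[i]),
          strand = as.character(BiocGenerics::strand(gr[i])),
          exon_start = BiocGenerics::start(gr[i]) - 1L + BiocGenerics::start(b) - 1L,
          exon_end = BiocGenerics::start(gr[i]) - 1L + BiocGenerics::end(b)
        )
      })
    }
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    ex <- gr[tolower(as.character(gr$type)) == "exon"]
    parents <- vapply(as.list(ex$Parent), function(p) {
      if (length(p) == 0) NA_character_ else sub("^transcript:", "", p[[1]])
    }, character(1))
    skipped <- sum(is.na(parents))
    if (skipped > 0) {
      warn(sprintf("skipped %d exon(s) without a parent transcript", skipped))
    }
    keep <- !is.na(parents)
    gene <- if (!is.null(ex$gene_id)) as.character(ex$gene_id) else {
      # fall back: transcript rows carry gene Parent; use transcript id
      parents
    }
    exons <- tibble(
      transcript_id = parents[keep],
      gene_id = gene[keep],
      strand = as.character(BiocGenerics::strand(ex))[keep],
      exon_start = BiocGenerics::start(ex)[keep] - 1L,
      exon_end = BiocGenerics::end(ex)[keep]
    )
    # resolve gene ids from transcript features when available
    tx <- gr[tolower(as.character(gr$type)) %in% c("mrna", "transcript")]
    if (length(tx) > 0 && !is.null(tx$ID)) {
      tx_gene <- vapply(as.list(tx$Parent), function(p) {
        if (length(p) == 0) NA_character_ else sub("^gene:", "", p[[1]])
      }, character(1))
      map <- setNames(tx_gene, sub("^transcript:", "", as.character(tx$ID)))
      hit <- exons$transcript_id %in% names(map)
      exons$gene_id[hit] <- unname(map[exons$transcript_id[hit]])
    }
  }
  exons <- exons %>%
    arrange(.data$transcript_id, .data$exon_start) %>%
    group_by(.data$transcript_id) %>%
    mutate(exon_rank = row_number()) %>%
    ungroup()
  bad <- exons %>%
    group_by(.data$transcript_id) %>%
    summarise(ovl = any(.data$exon_start[-1] < head(.data$exon_end, -1)),
              .groups = "drop") %>%
    filter(.data$ovl)
  if (nrow(bad) > 0) {
    abort(sprintf("overlapping exons within transcript(s): %s",
                  paste(bad$transcript_id, collapse = ", ")))
  }
  attr(exons, "skipped_orphans") <- skipped
  exons
}
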