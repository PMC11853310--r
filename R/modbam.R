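#' Read per-read modification calls from a modified-base alignment
#'
#' Parses SAM/BAM alignments carrying base-modification `MM`/`ML` auxiliary
#' tags and expands them into one row per modified-base probability call,
#' with reference coordinates derived from the alignment CIGAR (insertions
#' and soft clips yield no call; deletions produce no call). `MM` offsets are
#' interpreted in the original molecule orientation, so reverse-strand
#' alignments are traversed on the reverse complement of the stored sequence
#' and reported back on forward reference coordinates.
#'
#' @param path Path to a `.sam` (plain text) or `.bam` file.
#' @param mod_code Single-letter modification code to extract (`"a"` = m6A).
#' @return A tibble with columns `read_id`, `ref_id`, `pos` (0-based
#'   reference coordinate), `strand`, `base` (modified base in molecule
#'   sense, `A` for m6A) and `modProb` (decoded probability). The attribute
#'   `"skipped_unmapped"` counts unmapped records that were skipped.
#' @export
read_modbam <- function(path, mod_code = "a") {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  aln <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    read_alignments_bam(path)
  } else {
    read_alignments_sam(path)
  }
  n_unmapped <- sum(bitwAnd(aln$flag, 4L) != 0)
  aln <- aln[bitwAnd(aln$flag, 4L) == 0, , drop = FALSE]
  calls <- purrr::pmap(aln, function(qname, flag, rname, pos, cigar, seq, MM, ML) {
    expand_mm_read(qname, flag, rname, pos, cigar, seq, MM, ML, mod_code)
  })
  out <- bind_rows(calls)
  if (nrow(out) == 0) {
    out <- tibble(read_id = character(), ref_id = character(),
                  pos = integer(), strand = character(),
                  base = character(), modProb = numeric())
  }
  attr(out, "skipped_unmapped") <- n_unmapped
  out
}

read_alignments_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(qname = character(), flag = integer(), rname = character(),
                  pos = integer(), cigar = character(), seq = character(),
                  MM = character(), ML = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  grab_tag <- function(f, tags) {
    opt <- f[-(1:11)]
    hit <- opt[sub(":.*", "", opt) %in% tags]
    if (length(hit) == 0) NA_character_ else sub("^[A-Za-z][A-Za-z0-9]:[A-Za-z]:", "", hit[1])
  }
  tibble(
    qname = vapply(fields, `[`, character(1), 1),
    flag  = as.integer(vapply(fields, `[`, character(1), 2)),
    rname = vapply(fields, `[`, character(1), 3),
    pos   = as.integer(vapply(fields, `[`, character(1), 4)),
    cigar = vapply(fields, `[`, character(1), 6),
    seq   = vapply(fields, `[`, character(1), 10),
    MM    = vapply(fields, grab_tag, character(1), c("MM", "Mm")),
    ML    = lapply(fields, function(f) {
      raw <- grab_tag(f, c("ML", "Ml"))
      if (is.na(raw)) return(NULL)
      as.integer(strsplit(sub("^C,", "", raw), ",", fixed = TRUE)[[1]])
    })
  )
}

read_alignments_bam <- function(path) {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("MM", "ML", "Mm", "Ml"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  mm <- b$tag$MM %||% b$tag$Mm %||% rep(NA_character_, length(b$qname))
  ml <- b$tag$ML %||% b$tag$Ml %||% vector("list", length(b$qname))
  tibble(
    qname = b$qname,
    flag = as.integer(b$flag),
    rname = as.character(b$rname),
    pos = as.integer(b$pos),
    cigar = b$cigar,
    seq = as.character(b$seq),
    MM = as.character(mm),
    ML = lapply(seq_along(b$qname), function(i) {
      v <- if (is.list(ml)) ml[[i]] else ml[i]
      if (is.null(v) || all(is.na(v))) NULL else as.integer(v)
    })
  )
}

# Map 0-based query positions (SEQ orientation) to 0-based reference positions.
# Insertions/soft clips map to NA; hard clips consume nothing.
query_to_ref_map <- function(cigar, pos1) {
  ops <- parse_cigar(cigar)
  qlen <- sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
  map <- rep(NA_integer_, qlen)
  q <- 0L
  r <- pos1 - 1L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      map[(q + 1):(q + len)] <- r + 0:(len - 1)
      q <- q + len; r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len
    }
  }
  map
}

parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") abort("alignment has no CIGAR")
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^\\d+", "", toks))
}

# Split an MM tag into segments and pair each with its slice of ML bytes.
parse_mm_segments <- function(MM, ML) {
  segs <- strsplit(sub(";$", "", MM), ";", fixed = TRUE)[[1]]
  out <- list()
  offset <- 0L
  for (s in segs) {
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    head_part <- parts[1]
    deltas <- as.integer(parts[-1])
    base <- substr(head_part, 1, 1)
    codes <- sub("^[A-ZN][-+]", "", head_part)
    codes <- sub("[.?]$", "", codes)
    n <- length(deltas)
    bytes <- if (n > 0) ML[(offset + 1):(offset + n)] else integer(0)
    offset <- offset + n * nchar(codes)
    out[[length(out) + 1]] <- list(base = base, codes = codes,
                                   deltas = deltas, bytes = bytes)
  }
  attr(out, "ml_used") <- offset
  out
}

expand_mm_read <- function(qname, flag, rname, pos, cigar, seq, MM, ML,
                           mod_code) {
  if (is.na(MM) || MM == "") return(NULL)
  ML <- ML %||% integer(0)
  segs <- parse_mm_segments(MM, ML)
  if (attr(segs, "ml_used") != length(ML)) {
    abort(sprintf("read %s: MM tag lists %d probabilities but ML has %d",
                  qname, attr(segs, "ml_used"), length(ML)))
  }
  seg <- purrr::detect(segs, function(s) grepl(mod_code, s$codes, fixed = TRUE))
  if (is.null(seg) || length(seg$deltas) == 0) return(NULL)

  reverse <- bitwAnd(flag, 16L) != 0
  oseq <- if (reverse) revcomp(seq) else seq
  occ <- which(strsplit(oseq, "", fixed = TRUE)[[1]] == seg$base) # 1-based
  # delta-expand: delta d means "skip d occurrences, call the next one"
  idx <- cumsum(seg$deltas + 1L)
  if (length(occ) < max(idx)) {
    abort(sprintf("read %s: MM tag addresses %s #%d but read has only %d",
                  qname, seg$base, max(idx), length(occ)))
  }
  opos <- occ[idx] - 1L                  # 0-based, original orientation
  L <- nchar(seq)
  qpos <- if (reverse) L - 1L - opos else opos
  refmap <- query_to_ref_map(cigar, pos)
  refpos <- refmap[qpos + 1L]
  keep <- !is.na(refpos)
  if (!any(keep)) return(NULL)
  tibble(
    read_id = qname,
    ref_id = rname,
    pos = refpos[keep],
    strand = if (reverse) "-" else "+",
    base = chartr("T", "U", seg$base),
    modProb = decode_modprob(seg$bytes[keep])
  )
}

#' Write per-read modification calls into a modified-base SAM/BAM
#'
#' Encodes per-read modification-probability calls as `MM`/`ML` tags on a
#' set of template alignments. Each call must fall on a reference position
#' aligned in its read's template alignment and on an occurrence of the
#' modified base.
#'
#' @param calls Tibble with columns `read_id`, `ref_id`, `pos` (0-based
#'   reference coordinate) and `modProb` (as returned by [read_modbam()]).
#' @param template Tibble of template alignments with columns `read_id`,
#'   `ref_id`, `pos` (0-based leftmost reference coordinate), `strand`
#'   (`+`/`-`) and `seq` (sequence as stored, i.e. reference orientation);
#'   an optional `cigar` column defaults to ungapped (`<len>M`).
#' @param path Output path; `.bam` suffix converts via [Rsamtools::asBam()],
#'   otherwise plain SAM text is written.
#' @param mod_code Modification code (`"a"` = m6A on A).
#' @param ref_lengths Optional named integer vector of reference lengths for
#'   the SAM header; inferred from the alignments when absent.
#' @return `path`, invisibly.
#' @export
write_modbam <- function(calls, template, path, mod_code = "a",
                         ref_lengths = NULL) {
  check_columns(calls, c("read_id", "ref_id", "pos", "modProb"), "calls")
  check_columns(template, c("read_id", "ref_id", "pos", "strand", "seq"),
                "template")
  if (!"cigar" %in% names(template)) {
    template$cigar <- paste0(nchar(template$seq), "M")
  }
  mod_base <- toupper(names(MOD_BASE_FOR_CODE)[
    MOD_BASE_FOR_CODE == mod_code]) %||% "A"
  if (length(mod_base) == 0) mod_base <- "A"

  recs <- purrr::pmap_chr(template, function(read_id, ref_id, pos, strand,
                                             seq, cigar, ...) {
    my <- calls[calls$read_id == read_id, , drop = FALSE]
    reverse <- strand == "-"
    flag <- if (reverse) 16L else 0L
    tagstr <- ""
    if (nrow(my) > 0) {
      if (any(my$ref_id != ref_id)) {
        abort(sprintf("read %s: calls on a different reference than template",
                      read_id))
      }
      refmap <- query_to_ref_map(cigar, pos + 1L)
      qpos <- match(my$pos, refmap) - 1L      # 0-based query positions
      if (any(is.na(qpos))) {
        abort(sprintf("read %s: call at reference position %d not aligned in template",
                      read_id, my$pos[which(is.na(qpos))[1]]))
      }
      L <- nchar(seq)
      opos <- if (reverse) L - 1L - qpos else qpos
      oseq <- if (reverse) revcomp(seq) else seq
      obases <- strsplit(oseq, "", fixed = TRUE)[[1]]
      if (any(obases[opos + 1L] != mod_base)) {
        abort(sprintf("read %s: call at a non-%s base", read_id, mod_base))
      }
      ord <- order(opos)
      opos <- opos[ord]
      bytes <- encode_modprob(my$modProb[ord])
      occ <- which(obases == mod_base) - 1L
      ranks <- match(opos, occ)
      deltas <- diff(c(0L, ranks)) - 1L
      tagstr <- sprintf("\tMM:Z:%s+%s?,%s;\tML:B:C,%s",
                        mod_base, mod_code,
                        paste(deltas, collapse = ","),
                        paste(bytes, collapse = ","))
    }
    paste0(paste(read_id, flag, ref_id, pos + 1L, 60, cigar, "*", 0, 0,
                 seq, "*", sep = "\t"), tagstr)
  })

  if (is.null(ref_lengths)) {
    ends <- purrr::pmap_int(template, function(ref_id, pos, cigar, seq, ...) {
      ops <- parse_cigar(cigar)
      pos + sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
    })
    ref_lengths <- tapply(ends, template$ref_id, max)
  }
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                      as.integer(ref_lengths)))
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    sam <- tempfile(fileext = ".sam")
    writeLines(c(header, recs), sam)
    Rsamtools::asBam(sam, sub("\\.bam$", "", path),
                     overwrite = TRUE, indexDestination = FALSE)
    unlink(sam)
  } else {
    writeLines(c(header, recs), path)
  }
  invisible(path)
}

MOD_BASE_FOR_CODE <- c(A = "a", C = "m", T = "17802", G = "o")
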