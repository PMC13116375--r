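# Readers and writers for the plain-text formats the pipeline consumes:
# BED3/6, BEDPE, a minimal SV VCF 4.2 dialect, GFF-lite gene annotations,
# dense contact-matrix text, and interaction score tables.

#' Read / write BED intervals
#'
#' BED is tab-separated and 0-based half-open, matching the package's
#' internal convention, so coordinates pass through unchanged. BED6 name,
#' score and strand columns are kept when present.
#'
#' @param path File path.
#' @return Interval tibble.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  d <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  names(d) <- cols[seq_len(ncol(d))]
  d$chrom <- as.character(d$chrom)
  validate_intervals(d)
  d
}

#' @rdname read_bed
#' @param iv Interval tibble; columns beyond the BED6 set are dropped.
#' @export
write_bed <- function(iv, path) {
  validate_intervals(iv)
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(iv))
  # BED columns are positional: stop at the first absent one
  upto <- which(cumsum(!c("chrom", "start", "end", "name", "score",
                          "strand") %in% keep) == 0)
  readr::write_tsv(iv[, head(c("chrom", "start", "end", "name", "score",
                               "strand"), length(upto))],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write BEDPE loop anchors
#'
#' Two anchors per row; intra-chromosomal loops are stored with anchor1
#' ordered before anchor2.
#'
#' @param path File path.
#' @return Tibble with columns `chrom1,start1,end1,chrom2,start2,end2` and
#'   optional `name`, `score`, `genome_id`.
#' @export
read_bedpe <- function(path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score")
  d <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  names(d) <- cols[seq_len(ncol(d))]
  d$chrom1 <- as.character(d$chrom1); d$chrom2 <- as.character(d$chrom2)
  validate_loops(d)
  d
}

#' @rdname read_bedpe
#' @param loops Loop tibble.
#' @export
write_bedpe <- function(loops, path) {
  validate_loops(loops)
  keep <- intersect(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "name", "score"), names(loops))
  readr::write_tsv(loops[, keep], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

validate_loops <- function(loops) {
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (!all(req %in% names(loops))) {
    abort(paste("loop table needs columns:", paste(req, collapse = ", ")))
  }
  if (any(loops$start1 >= loops$end1 | loops$start2 >= loops$end2)) {
    abort("loop anchors must satisfy start < end")
  }
  intra <- loops$chrom1 == loops$chrom2
  if (any(intra & loops$start1 > loops$start2)) {
    abort("intra-chromosomal loops must have anchor1 ordered before anchor2")
  }
  invisible(loops)
}

anchor1 <- function(loops) {
  tibble(chrom = loops$chrom1, start = loops$start1, end = loops$end1)
}
anchor2 <- function(loops) {
  tibble(chrom = loops$chrom2, start = loops$start2, end = loops$end2)
}

#' Read / write a minimal structural-variant VCF
#'
#' VCFv4.2 dialect: `SVTYPE`, `END` and `SVLEN` in INFO, `GT:DP:GQ` FORMAT.
#' Returned (and expected) as a tibble with one row per record: `chrom`,
#' `start` (0-based), `end`, `sv_type`, `size`, `id`, plus one
#' `GT`/`DP`/`GQ` triple per sample folded into the list column `genotypes`
#' (a tibble per record with `sample`, `gt`, `dp`, `gq`). INS records are
#' stored as points (`end = start + 1`) with `size` = inserted length.
#'
#' @param path File path.
#' @return SV tibble.
#' @export
read_sv_vcf <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) abort("no #CHROM header line in VCF")
  fields <- strsplit(lines[hdr], "\t")[[1]]
  samples <- if (length(fields) > 9) fields[-(1:9)] else character()
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  rows <- map(body, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    info <- strsplit(f[8], ";")[[1]]
    kv <- strsplit(info, "=")
    info_v <- setNames(vapply(kv, \(x) x[2] %||% NA_character_, ""),
                       vapply(kv, \(x) x[1], ""))
    pos <- as.numeric(f[2]) - 1          # VCF is 1-based
    svtype <- info_v[["SVTYPE"]]
    end <- if (!is.na(info_v["END"])) as.numeric(info_v[["END"]]) else pos + 1
    size <- abs(as.numeric(info_v["SVLEN"] %||% NA))
    gt <- NULL
    if (length(samples)) {
      gfields <- map(f[-(1:9)], \(s) strsplit(s, ":")[[1]])
      gt <- tibble(sample = samples,
                   gt = map_chr(gfields, 1),
                   dp = as.numeric(map_chr(gfields, \(x) x[2] %||% NA)),
                   gq = as.numeric(map_chr(gfields, \(x) x[3] %||% NA)))
    }
    tibble(chrom = f[1], start = pos,
           end = if (svtype == "INS") pos + 1 else end,
           sv_type = svtype, size = size, id = f[3],
           genotypes = list(gt))
  })
  list_rbind(rows)
}

#' @rdname read_sv_vcf
#' @param svs SV tibble as returned by [read_sv_vcf()].
#' @export
write_sv_vcf <- function(svs, path) {
  samples <- if (nrow(svs) && !is.null(svs$genotypes[[1]])) {
    svs$genotypes[[1]]$sample
  } else character()
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Qual\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- pmap(svs, function(chrom, start, end, sv_type, size, id,
                             genotypes, ...) {
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", sv_type, as.integer(end),
                    as.integer(if (sv_type == "DEL") -size else size))
    gcols <- if (!is.null(genotypes)) {
      sprintf("%s:%d:%d", genotypes$gt, as.integer(genotypes$dp),
              as.integer(genotypes$gq))
    } else character()
    paste(c(chrom, start + 1, id, "N", paste0("<", sv_type, ">"), ".",
            "PASS", info, "GT:DP:GQ", gcols), collapse = "\t")
  })
  readr::write_lines(c(hdr, unlist(body)), path)
  invisible(path)
}

#' Read / write GFF-lite gene annotations
#'
#' A reduced GFF3: seqid, source, type, start, end, score, strand, frame,
#' attributes (`ID=`). 1-based inclusive coordinates are converted to the
#' package's 0-based half-open convention on read. The TSS is derived from
#' strand: `start` for `+`, `end - 1` for `-`.
#'
#' @param path File path.
#' @return Tibble `chrom,start,end,strand,gene_id,tss`.
#' @export
read_genes_gff <- function(path) {
  d <- readr::read_tsv(path, col_names = c("chrom", "source", "type",
                                           "start", "end", "score", "strand",
                                           "frame", "attr"),
                       comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  d <- d[d$type == "gene", ]
  gene_table(chrom = as.character(d$chrom), start = d$start - 1, end = d$end,
             strand = d$strand,
             gene_id = sub(".*ID=([^;]+).*", "\\1", d$attr))
}

#' Assemble a gene table with TSS positions
#'
#' @param chrom,start,end 0-based half-open gene spans.
#' @param strand "+" or "-".
#' @param gene_id Unique identifiers.
#' @return Tibble with a derived `tss` column (0-based position).
#' @export
gene_table <- function(chrom, start, end, strand, gene_id) {
  iv <- intervals(chrom, start, end, strand = strand, gene_id = gene_id)
  iv$tss <- ifelse(iv$strand == "-", iv$end - 1, iv$start)
  iv
}

#' @rdname read_genes_gff
#' @param genes Gene tibble from [gene_table()].
#' @export
write_genes_gff <- function(genes, path) {
  lines <- sprintf("%s\tpanchrom3d\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, as.integer(genes$start + 1),
                   as.integer(genes$end), genes$strand, genes$gene_id)
  readr::write_lines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read / write a dense contact matrix
#'
#' Whitespace-separated dense text; a `# chrom=<name> bin_size=<bp>` comment
#' line carries the bin metadata.
#'
#' @param path File path.
#' @return A [contact_matrix()] object.
#' @export
read_contact_matrix <- function(path) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  meta <- regmatches(first, gregexpr("(chrom|bin_size)=[^ ]+", first))[[1]]
  kv <- setNames(sub(".*=", "", meta), sub("=.*", "", meta))
  M <- as.matrix(utils::read.table(path, comment.char = "#"))
  dimnames(M) <- NULL
  storage.mode(M) <- "double"
  contact_matrix(M, chrom = kv[["chrom"]],
                 bin_size = as.numeric(kv[["bin_size"]]))
}

#' @rdname read_contact_matrix
#' @param cm A [contact_matrix()] object.
#' @export
write_contact_matrix <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chrom=%s bin_size=%d", cm$chrom,
                     as.integer(cm$bin_size)), con)
  utils::write.table(cm$M, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate a dataset against declared chromosome sizes
#'
#' Fails fast with per-file diagnostics: start/end sanity, coordinates inside
#' the declared chromosome, format sniffing by column count.
#'
#' @param paths Named character vector of file paths (names = roles, any of
#'   `bed`, `bedpe`, `vcf`).
#' @param genome [genome_coords()] tibble.
#' @param stop_on_error Abort (default) with the first diagnostics rather
#'   than returning them.
#' @return A tibble report, zero rows when everything is valid.
#' @export
validate_inputs <- function(paths, genome, stop_on_error = TRUE) {
  problems <- list()
  note <- function(file, line, msg) {
    problems[[length(problems) + 1]] <<- tibble(file = file, line = line,
                                                problem = msg)
  }
  check_iv <- function(d, file, line_offset = 0) {
    bad <- which(d$start >= d$end)
    for (i in bad) note(file, i + line_offset, "start >= end")
    g <- genome$length[match(d$chrom, genome$chrom)]
    bad <- which(is.na(g))
    for (i in bad) note(file, i + line_offset, "unknown chromosome")
    bad <- which(!is.na(g) & (d$start < 0 | d$end > g))
    for (i in bad) note(file, i + line_offset, "interval beyond chrom size")
  }
  for (role in names(paths)) {
    p <- paths[[role]]
    if (!file.exists(p)) { note(p, NA, "file not found"); next }
    res <- tryCatch({
      if (role == "bedpe") {
        d <- read_bedpe(p)
        check_iv(anchor1(d), p); check_iv(anchor2(d), p)
      } else if (role == "vcf") {
        d <- read_sv_vcf(p)
        check_iv(d[c("chrom", "start", "end")], p)
      } else {
        d <- readr::read_tsv(p, col_names = FALSE, comment = "#",
                             show_col_types = FALSE, progress = FALSE)
        names(d)[1:3] <- c("chrom", "start", "end")
        d$chrom <- as.character(d$chrom)
        check_iv(d, p)
      }
      NULL
    }, error = function(e) note(p, NA, conditionMessage(e)))
  }
  report <- if (length(problems)) list_rbind(problems) else {
    tibble(file = character(), line = numeric(), problem = character())
  }
  if (stop_on_error && nrow(report)) {
    abort(paste0("invalid input: ",
                 paste(sprintf("%s line %s: %s", report$file,
                               ifelse(is.na(report$line), "?", report$line),
                               report$problem),
                       collapse = "; ")))
  }
  report
}
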