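#' Construct and validate a marker map
#'
#' A marker map is a `data.frame` with one row per SNP and columns
#' `marker_id`, `chrom`, `pos` (1-based bp), `ref` and `alt` (single bases).
#' Markers must be strictly sorted by (chrom, pos) with no duplicate
#' positions or ids, and ref/alt must be distinct bases in A/C/G/T.
#'
#' @param marker_id character vector of unique marker names.
#' @param chrom character chromosome identifiers.
#' @param pos integer 1-based positions.
#' @param ref,alt single-character reference/alternate alleles.
#' @return A validated `data.frame` of class `marker_map`.
#' @export
marker_map <- function(marker_id, chrom, pos, ref, alt) {
  map <- data.frame(marker_id = as.character(marker_id),
                    chrom = as.character(chrom),
                    pos = as.integer(pos),
                    ref = as.character(ref), alt = as.character(alt),
                    stringsAsFactors = FALSE)
  validate_marker_map(map)
}

validate_marker_map <- function(map) {
  if (anyDuplicated(map$marker_id))
    hd_validation_error("duplicate marker_id in marker map")
  key <- paste(map$chrom, map$pos)
  if (anyDuplicated(key))
    hd_validation_error("duplicate (chrom, pos) in marker map")
  o <- order(map$chrom, map$pos)
  if (!identical(o, seq_len(nrow(map))))
    hd_validation_error("marker map not sorted by (chrom, pos)")
  if (nrow(map) > 0) {
    if (!all(map$ref %in% DNA_BASES) || !all(map$alt %in% DNA_BASES))
      hd_validation_error("marker alleles must be single bases in A/C/G/T")
    if (any(map$ref == map$alt))
      hd_validation_error("ref and alt allele identical for some markers")
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Construct a phased genotype matrix
#'
#' Container for per-animal, per-marker ordered allele pairs. Alleles are
#' coded 0 (reference), 1 (alternate) or `NA` (missing); `hap_a` holds the
#' left-hand (first-written) allele of each genotype, `hap_b` the right.
#' A phased matrix must be complete (no missing codes).
#'
#' @param animal_ids character vector of animal identifiers (one per row).
#' @param map a [marker_map()] (one row per column of the matrices).
#' @param hap_a,hap_b integer matrices (animals x markers) of 0/1/NA codes.
#' @param phased logical; `TRUE` only for fully phased, complete data.
#' @return An object of class `hap_genotypes`.
#' @export
hap_genotypes <- function(animal_ids, map, hap_a, hap_b, phased = TRUE) {
  animal_ids <- as.character(animal_ids)
  if (anyDuplicated(animal_ids))
    hd_validation_error("duplicate animal ids")
  hap_a <- as.matrix(hap_a); hap_b <- as.matrix(hap_b)
  if (!all(dim(hap_a) == c(length(animal_ids), nrow(map))) ||
      !all(dim(hap_b) == dim(hap_a)))
    hd_validation_error("haplotype matrix dimensions inconsistent with animals x markers")
  ok <- function(m) all(m %in% c(0L, 1L) | is.na(m))
  if (!ok(hap_a) || !ok(hap_b))
    hd_validation_error("allele codes must be 0, 1 or NA")
  if (phased && (anyNA(hap_a) || anyNA(hap_b)))
    hd_validation_error("phased genotype matrix may not contain missing codes")
  dimnames(hap_a) <- dimnames(hap_b) <- list(animal_ids, map$marker_id)
  structure(list(animal_ids = animal_ids, map = map,
                 hap_a = hap_a, hap_b = hap_b, phased = phased),
            class = "hap_genotypes")
}

#' @export
print.hap_genotypes <- function(x, ...) {
  cat(sprintf("<hap_genotypes> %d animals x %d markers (%s)\n",
              length(x$animal_ids), nrow(x$map),
              if (x$phased) "phased" else "unphased"))
  invisible(x)
}

#' Number of animals / markers in a genotype matrix
#' @param g a `hap_genotypes` object.
#' @return integer count.
#' @export
n_animals <- function(g) length(g$animal_ids)

#' @rdname n_animals
#' @export
n_markers <- function(g) nrow(g$map)

vcf_sample_ids <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0)
      hd_parse_error(sprintf("%s: no #CHROM header line found", path))
    if (startsWith(line, "#CHROM")) break
    if (!startsWith(line, "##"))
      hd_parse_error(sprintf("%s: malformed header line before #CHROM: '%s'",
                             path, substr(line, 1, 40)))
  }
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 9 ||
      !identical(fields[1:9], c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                "FILTER", "INFO", "FORMAT")))
    hd_parse_error(sprintf("%s: #CHROM line lacks the 9 mandatory columns", path))
  fields[-(1:9)]
}

read_vcf_body <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) hd_parse_error(
                  sprintf("%s: VCF parse failure: %s", path, conditionMessage(e))))
  v
}

#' Read phased genotypes from a VCF file
#'
#' Reads a VCF v4.2 file with GT calls into a [hap_genotypes()] matrix.
#' Only biallelic SNV records are retained; multi-allelic or indel records
#' are skipped with a counted warning. The written allele order is kept:
#' the left allele of each GT goes to `hap_a`.
#'
#' @param path path to a VCF file (plain text).
#' @param require_phase if `TRUE` (default) any unphased ("/") or missing GT
#'   raises a phase error and the result is marked phased.
#' @return A `hap_genotypes` object.
#' @export
read_phased_vcf <- function(path, require_phase = TRUE) {
  samples <- vcf_sample_ids(path)
  v <- read_vcf_body(path)
  fix <- v@fix
  if (nrow(fix) == 0) {
    empty <- matrix(integer(0), nrow = length(samples), ncol = 0)
    map <- validate_marker_map(data.frame(marker_id = character(0),
                                          chrom = character(0), pos = integer(0),
                                          ref = character(0), alt = character(0)))
    return(hap_genotypes(samples, map, empty, empty, phased = require_phase))
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% DNA_BASES & alt %in% DNA_BASES
  if (sum(!keep) > 0)
    warning(sprintf("%s: skipped %d non-biallelic/non-SNV record(s)",
                    path, sum(!keep)))
  gt <- vcfR::extract.gt(v)
  if (is.null(gt))
    hd_parse_error(sprintf("%s: no GT field present", path))
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  ids <- fix[, "ID"]
  if (anyNA(ids)) {
    auto <- paste0("snp_", fix[, "CHROM"], "_", fix[, "POS"])
    ids[is.na(ids)] <- auto[is.na(ids)]
  }
  map <- validate_marker_map(data.frame(
    marker_id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], stringsAsFactors = FALSE))
  unphased <- grepl("/", gt, fixed = TRUE)
  missing <- is.na(gt) | gt %in% c(".", ".|.", "./.")
  if (require_phase && any(unphased | missing)) {
    bad <- which(unphased | missing, arr.ind = TRUE)[1, ]
    hd_phase_error(sprintf(
      "%s: unphased or missing GT at marker %s, sample %s but phase required",
      path, rownames(gt)[bad[1]] %||% map$marker_id[bad[1]],
      colnames(gt)[bad[2]]))
  }
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  to_code <- function(a) {
    out <- rep(NA_integer_, length(a))
    out[!is.na(a) & a == "0"] <- 0L
    out[!is.na(a) & a == "1"] <- 1L
    bad <- setdiff(unique(a[!is.na(a)]), c("0", "1", ".", ""))
    if (length(bad) > 0)
      hd_parse_error(sprintf("%s: unexpected allele code '%s' in GT field",
                             path, bad[1]))
    out
  }
  nm <- nrow(gt); ns <- ncol(gt)
  hap_a <- t(matrix(to_code(a1), nrow = nm, ncol = ns))
  hap_b <- t(matrix(to_code(a2), nrow = nm, ncol = ns))
  hap_b[t(missing)] <- NA_integer_; hap_a[t(missing)] <- NA_integer_
  hap_genotypes(samples, map, hap_a, hap_b, phased = require_phase)
}

#' Write phased genotypes to a VCF file
#'
#' Emits a minimal VCF v4.2 with GT-only genotype columns; the exact
#' inverse of [read_phased_vcf()] for valid matrices.
#'
#' @param g a `hap_genotypes` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(g, path) {
  sep <- if (g$phased) "|" else "/"
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", unique(g$map$chrom)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$animal_ids), collapse = "\t"))
  lines <- header
  if (nrow(g$map) > 0) {
    code <- function(m) { x <- as.character(m); x[is.na(x)] <- "."; x }
    gtmat <- matrix(paste(code(g$hap_a), code(g$hap_b), sep = sep),
                    nrow = n_animals(g))
    body <- vapply(seq_len(nrow(g$map)), function(j) {
      paste(c(g$map$chrom[j], g$map$pos[j], g$map$marker_id[j], g$map$ref[j],
              g$map$alt[j], ".", "PASS", ".", "GT", gtmat[, j]),
            collapse = "\t")
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a sequence-variant panel
#'
#' Holds sequence-level variant calls for a sequenced sample subset:
#' a variant table (`chrom`, `pos`, `ref`, `alt`, `qual`, `annotatable`)
#' plus an alternate-allele dosage matrix (variants x samples, entries
#' 0/1/2/NA). Records that are not biallelic SNVs are carried but flagged
#' `annotatable = FALSE`.
#'
#' @param variants data.frame with columns chrom, pos, ref, alt, qual.
#' @param dosages integer matrix (variants x samples) of alt-allele counts.
#' @return An object of class `seq_panel`.
#' @export
seq_panel <- function(variants, dosages) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != nrow(variants))
    hd_validation_error("dosage matrix rows must match variant table rows")
  if (!all(dosages %in% c(0L, 1L, 2L) | is.na(dosages)))
    hd_validation_error("dosages must be 0, 1, 2 or NA")
  variants$annotatable <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref %in% DNA_BASES & variants$alt %in% DNA_BASES
  structure(list(variants = variants, dosages = dosages,
                 sample_ids = colnames(dosages)),
            class = "seq_panel")
}

#' @export
print.seq_panel <- function(x, ...) {
  cat(sprintf("<seq_panel> %d variants x %d samples (%d annotatable SNVs)\n",
              nrow(x$variants), length(x$sample_ids), sum(x$variants$annotatable)))
  invisible(x)
}

#' Read sequence variants (with dosages) from a VCF file
#'
#' All records are retained; non-SNV records are flagged non-annotatable.
#' Dosages are alternate-allele counts derived from GT (NA when any allele
#' is missing).
#'
#' @param path path to a VCF file.
#' @return A [seq_panel()] object.
#' @export
read_variant_vcf <- function(path) {
  samples <- vcf_sample_ids(path)
  v <- read_vcf_body(path)
  fix <- v@fix
  if (nrow(fix) == 0)
    return(seq_panel(data.frame(chrom = character(0), pos = integer(0),
                                ref = character(0), alt = character(0),
                                qual = numeric(0)),
                     matrix(integer(0), 0, length(samples),
                            dimnames = list(NULL, samples))))
  gt <- vcfR::extract.gt(v)
  if (is.null(gt)) hd_parse_error(sprintf("%s: no GT field present", path))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  variants <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"], qual = qual,
                         stringsAsFactors = FALSE)
  miss <- is.na(gt) | gt %in% c(".", ".|.", "./.")
  n1 <- (substr(gt, 1, 1) == "1") + (substr(gt, 3, 3) == "1")
  n1[miss] <- NA_integer_
  dos <- matrix(as.integer(n1), nrow = nrow(gt),
                dimnames = list(NULL, colnames(gt)))
  seq_panel(variants, dos[, samples, drop = FALSE])
}

#' Write a sequence-variant panel to a VCF file
#' @param panel a `seq_panel` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(panel, path) {
  va <- panel$variants
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", unique(va$chrom)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$sample_ids), collapse = "\t"))
  gt_of <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(va)), function(i) {
    d <- panel$dosages[i, ]
    gts <- ifelse(is.na(d), "./.", gt_of[d + 1L])
    paste(c(va$chrom[i], va$pos[i], sprintf("var_%s_%d", va$chrom[i], va$pos[i]),
            va$ref[i], va$alt[i],
            if (is.na(va$qual[i])) "." else format(va$qual[i], digits = 6),
            "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
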