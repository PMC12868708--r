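# Reading and writing the standard formats the pipeline touches: a minimal
# two-record VCF for the HFE genotypes, and TSV for diagnosis-count tables.

#' Canonical definitions of the two pathogenic HFE variants
#'
#' GRCh38, 1-based: chr6:26092913 G>A (p.Cys282Tyr) and chr6:26090951 C>G
#' (p.His63Asp).
#'
#' @return data frame with columns `label`, `chrom`, `pos`, `ref`, `alt`.
#' @export
hfe_variants <- function() {
  data.frame(
    label = c("C282Y", "H63D"),
    chrom = "chr6",
    pos = c(26092913L, 26090951L),
    ref = c("G", "C"),
    alt = c("A", "G"),
    stringsAsFactors = FALSE
  )
}

# allele dosage at each site per genotype class -> GT string
dose_to_gt <- function(d) c("0/0", "0/1", "1/1")[d + 1L]

#' Write a cohort as a minimal VCF
#'
#' Emits VCFv4.2 with exactly the two canonical biallelic HFE records
#' (position-sorted) and unphased diploid GTs.  Samples are ordered by id,
#' so output is deterministic.
#'
#' @param cohort an `hfe_cohort` (see [simulate_genotypes()]).
#' @param path output path.
#' @param meta optional extra `##`-prefixed header lines (e.g. a seed echo).
#' @return `path`, invisibly.
#' @export
write_hfe_vcf <- function(cohort, path, meta = character(0)) {
  stopifnot(inherits(cohort, "hfe_cohort") || is.data.frame(cohort))
  cohort <- cohort[order(cohort$id), , drop = FALSE]
  gidx <- match(as.character(cohort$genotype), GENOTYPE_CLASSES)
  stopifnot(!anyNA(gidx))
  v <- hfe_variants()
  v <- v[order(v$pos), ]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hfeRisk",
    "##contig=<ID=chr6>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    meta,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$id), collapse = "\t")
  )
  records <- vapply(seq_len(nrow(v)), function(i) {
    dose <- if (v$label[i] == "C282Y") C282Y_DOSE[gidx] else H63D_DOSE[gidx]
    paste(c(v$chrom[i], v$pos[i], v$label[i], v$ref[i], v$alt[i],
            ".", ".", ".", "GT", dose_to_gt(dose)), collapse = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read HFE genotypes from a VCF
#'
#' Parses a VCF containing the two canonical HFE records (matched by
#' chromosome/position/ref/alt; "chr" prefixes are ignored) and maps every
#' sample to one of the six triallelic genotype classes.  Samples with a
#' missing GT at either site are excluded and counted; samples whose GTs
#' imply more than two pathogenic alleles (e.g. 1/1 plus 0/1) are excluded
#' with a warning.
#'
#' @param path VCF path.
#' @param region_map named character vector (sample id -> region), or a data
#'   frame with columns `id` and `region`.  Every retained sample must be
#'   covered.
#' @return an `hfe_cohort`, with attribute `excluded` summarising dropped
#'   samples.
#' @export
read_hfe_vcf <- function(path, region_map) {
  if (is.data.frame(region_map)) {
    region_map <- setNames(as.character(region_map$region),
                           as.character(region_map$id))
  }
  vcf <- VariantAnnotation::readVcf(path, genome = "GRCh38")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- sub("^chr", "", as.character(GenomeInfoDb::seqnames(rr)))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  alt <- vapply(as.list(rr$ALT), function(a) paste(as.character(a),
                collapse = ","), character(1))
  v <- hfe_variants()
  site_row <- function(lab) {
    d <- v[v$label == lab, ]
    hit <- which(chrom == sub("^chr", "", d$chrom) & pos == d$pos &
                   ref == d$ref & alt == d$alt)
    if (length(hit) != 1) {
      stop("VCF is missing the canonical ", lab, " record (",
           d$chrom, ":", d$pos, " ", d$ref, ">", d$alt, ")", call. = FALSE)
    }
    hit
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  dose1 <- function(g) {
    # diploid unphased/phased GT string -> ALT dosage; NA when missing
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  }
  dc <- vapply(gt[site_row("C282Y"), ], dose1, integer(1))
  dh <- vapply(gt[site_row("H63D"), ], dose1, integer(1))
  ids <- colnames(gt)
  missing <- is.na(dc) | is.na(dh)
  overdosed <- !missing & (dc + dh > 2)
  if (any(overdosed)) {
    warning(sum(overdosed), " sample(s) carry >2 pathogenic alleles across ",
            "the two sites and were excluded: ",
            paste(ids[overdosed], collapse = ", "), call. = FALSE)
  }
  keep <- !missing & !overdosed
  if (any(missing)) {
    message(sum(missing), " sample(s) excluded for missing GT")
  }
  cls <- character(sum(keep))
  dck <- dc[keep]; dhk <- dh[keep]
  cls[dck == 0 & dhk == 0] <- "WT/WT"
  cls[dck == 1 & dhk == 0] <- "WT/C282Y"
  cls[dck == 0 & dhk == 1] <- "WT/H63D"
  cls[dck == 2 & dhk == 0] <- "C282Y/C282Y"
  cls[dck == 1 & dhk == 1] <- "C282Y/H63D"
  cls[dck == 0 & dhk == 2] <- "H63D/H63D"
  kept_ids <- ids[keep]
  unmapped <- setdiff(kept_ids, names(region_map))
  if (length(unmapped)) {
    stop("no region label for sample(s): ",
         paste(utils::head(unmapped, 5), collapse = ", "),
         if (length(unmapped) > 5) " ..." else "", call. = FALSE)
  }
  out <- data.frame(
    id = kept_ids,
    region = unname(region_map[kept_ids]),
    genotype = factor(cls, levels = GENOTYPE_CLASSES),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("hfe_cohort", "data.frame")
  attr(out, "excluded") <- list(missing = ids[missing],
                                multi_alt = ids[overdosed])
  out
}

# strip thousands separators and percent signs, as printed tables carry both
strip_numeric <- function(x) as.numeric(gsub("[,%[:space:]]", "", x))

#' Read a diagnosis-count table
#'
#' TSV with header columns `stratum`, `count`, `denominator` (thousands
#' separators tolerated).  Counts exceeding their denominator are an error;
#' counts that are not multiples of 5 trigger a warning, since national EHR
#' feasibility extracts are disclosure-rounded to increments of 5.
#'
#' @param path TSV path.
#' @param warn_unrounded warn when counts are not multiples of 5
#'   (default `TRUE`).
#' @return a `diagnosis_table` data frame.
#' @export
read_counts_table <- function(path, warn_unrounded = TRUE) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("stratum", "count", "denominator")
  if (!all(need %in% names(raw))) {
    stop("counts table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    stratum = raw$stratum,
    count = as.integer(strip_numeric(raw$count)),
    denominator = as.integer(strip_numeric(raw$denominator)),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$count) || anyNA(out$denominator)) {
    stop("non-numeric count or denominator in ", path, call. = FALSE)
  }
  if (any(out$count < 0) || any(out$denominator <= 0)) {
    stop("counts must be >= 0 and denominators > 0", call. = FALSE)
  }
  bad <- out$count > out$denominator
  if (any(bad)) {
    stop("count exceeds denominator for stratum: ",
         paste(out$stratum[bad], collapse = ", "), call. = FALSE)
  }
  if (warn_unrounded && any(out$count %% 5 != 0)) {
    warning(sum(out$count %% 5 != 0),
            " count(s) are not multiples of 5", call. = FALSE)
  }
  class(out) <- c("diagnosis_table", "data.frame")
  out
}

#' Write a diagnosis-count table as TSV
#'
#' @param table a `diagnosis_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(table, path) {
  stopifnot(is.data.frame(table),
            all(c("stratum", "count", "denominator") %in% names(table)))
  utils::write.table(table[, c("stratum", "count", "denominator")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
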