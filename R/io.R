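#' @importFrom utils read.delim write.table
NULL

#' Read sample panels from Ct / MSI marker tables
#'
#' The Ct table has one row per sample with columns \code{sample_id},
#' \code{role}, \code{ct_18s}, \code{ct_ebna1} and \code{ct_<GENE>} for the
#' signature genes; the optional MSI table adds the five pentaplex marker
#' call columns (\code{marker_<LOCUS>}, states identical /
#' additional_alleles / missing) and \code{mlh1_homogeneous} /
#' \code{mlh1_mutated} flags; an optional SCNA table adds
#' \code{scna_total}.
#'
#' @param ctPath path to the Ct TSV.
#' @param msiPath optional path to the MSI marker TSV.
#' @param scnaPath optional path to a TSV with sample_id, scna_total.
#' @return list of \linkS4class{SamplePanel}s.
#' @export
readSamplePanels <- function(ctPath, msiPath = NULL, scnaPath = NULL) {
  ct <- read.delim(ctPath, stringsAsFactors = FALSE, check.names = FALSE)
  msi <- if (!is.null(msiPath))
    read.delim(msiPath, stringsAsFactors = FALSE, check.names = FALSE)
  scna <- if (!is.null(scnaPath))
    read.delim(scnaPath, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(ct)), function(i) {
    row <- ct[i, ]
    genes <- intersect(CT_GENES, toupper(sub("^ct_", "",
                                             names(ct)[grep("^ct_", names(ct))])))
    ctv <- setNames(vapply(genes, function(g)
      as.numeric(row[[paste0("ct_", g)]]), numeric(1)), genes)
    ctv <- ctv[!is.na(ctv)]
    markers <- character()
    mlh1h <- NA
    mlh1m <- NA
    if (!is.null(msi)) {
      mrow <- msi[msi$sample_id == row$sample_id, , drop = FALSE]
      if (nrow(mrow) == 1) {
        cols <- paste0("marker_", PENTAPLEX_LOCI)
        if (all(cols %in% names(mrow)))
          markers <- setNames(vapply(cols, function(cn)
            as.character(mrow[[cn]]), character(1)), PENTAPLEX_LOCI)
        if ("mlh1_homogeneous" %in% names(mrow))
          mlh1h <- as.logical(mrow$mlh1_homogeneous)
        if ("mlh1_mutated" %in% names(mrow))
          mlh1m <- as.logical(mrow$mlh1_mutated)
      }
    }
    sc <- NA_real_
    if (!is.null(scna)) {
      srow <- scna[scna$sample_id == row$sample_id, , drop = FALSE]
      if (nrow(srow) == 1) sc <- as.numeric(srow$scna_total)
    }
    SamplePanel(sampleId = row$sample_id,
                role = if ("role" %in% names(row)) row$role else "tumor",
                ct = ctv, ct18s = as.numeric(row$ct_18s),
                ctEbna1 = if ("ct_ebna1" %in% names(row))
                  as.numeric(row$ct_ebna1) else 40,
                msiMarkers = markers, mlh1Homogeneous = mlh1h,
                mlh1Mutated = mlh1m, scna = sc)
  })
}

#' Read a variant table (TSV or VCF)
#'
#' TSV tables need the core columns chrom, pos, ref, alt, depth,
#' alt_support. VCF 4.x files are parsed with the vcfR package when
#' installed; depth and support are taken from the INFO keys \code{DP} and
#' \code{AO} (or \code{AF} x \code{DP}); \code{IMPACT} and the population
#' annotation keys are honored when present.
#'
#' @param path input file; format by extension (\code{.vcf} vs anything
#'   else as TSV).
#' @param normalize apply key normalization (multi-allelic split +
#'   parsimony trim; default TRUE).
#' @return a \linkS4class{VariantSet}.
#' @export
readVariantTable <- function(path, normalize = TRUE) {
  df <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    info1 <- function(key) {
      x <- vcfR::extract.info(v, element = key)
      suppressWarnings(as.numeric(x))
    }
    dp <- info1("DP")
    ao <- info1("AO")
    af <- info1("AF")
    if (all(is.na(ao)) && !all(is.na(af))) ao <- round(af * dp)
    imp <- vcfR::extract.info(v, element = "IMPACT")
    data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
               ref = fix$REF, alt = fix$ALT,
               depth = dp, alt_support = ao,
               impact = tolower(imp),
               hapmap_ac = info1("HAPMAP_AC"),
               cgi69_ac = info1("CGI69_AC"),
               evs1000_ac = info1("EVS1000_AC"),
               dbsnp_max_maf = info1("DBSNP_MAX_MAF"),
               stringsAsFactors = FALSE)
  } else read.delim(path, stringsAsFactors = FALSE)
  if (normalize) normalizeVariants(df) else VariantSet(df)
}

#' Write a variant set
#'
#' TSV by default; with \code{format = "vcf"} a minimal VCF 4.2 file is
#' emitted carrying depth, support, callers, impact and population
#' annotations as INFO keys (readable back via
#' \code{\link{readVariantTable}}).
#'
#' @param vs a \linkS4class{VariantSet}.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @return \code{path}, invisibly.
#' @export
writeVariantTable <- function(vs, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  v <- variants(vs)
  if (format == "tsv") {
    write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  info_of <- function(i) {
    keys <- c(DP = v$depth[i], AO = v$alt_support[i])
    extra <- c(IMPACT = if (!is.na(v$impact[i])) toupper(v$impact[i]),
               CALLERS = if (!is.null(v$callers) && !is.na(v$callers[i]))
                 gsub(",", "|", v$callers[i]))
    paste(c(paste0(names(keys), "=", keys),
            if (length(extra)) paste0(names(extra), "=", extra)),
          collapse = ";")
  }
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
             "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alt support\">",
             "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Impact\">",
             "##INFO=<ID=CALLERS,Number=1,Type=String,Description=\"Callers\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(v))
    lines <- c(lines, vapply(seq_len(nrow(v)), function(i)
      paste(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS",
            info_of(i), sep = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-gene copy-number TSV
#'
#' Columns: gene, chrom, copy_number and either length or start/end.
#'
#' @param path input TSV.
#' @return a \linkS4class{CopyNumberProfile}.
#' @export
readCnTable <- function(path) {
  CopyNumberProfile(read.delim(path, stringsAsFactors = FALSE))
}

#' Read a droplet-count TSV
#'
#' Columns: assay, mutant_droplets, wt_droplets, total.
#'
#' @param path input TSV.
#' @return data.frame of droplet counts per assay.
#' @export
readDropletTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a cohort annotation TSV
#'
#' @param path TSV with per-patient rows, requiring \code{id} and logical
#'   (or TRUE/FALSE-coded) \code{engrafted}.
#' @return a \linkS4class{CohortTable}.
#' @export
readCohortTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$engrafted <- as.logical(df$engrafted)
  CohortTable(df)
}
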