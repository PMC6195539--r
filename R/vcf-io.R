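#' Write a cohort to VCF
#'
#' Emits VCF v4.2 with `FORMAT GT:GQ:AD` and the INFO keys `GENE`,
#' `CSQ_CLASS`, `CADD`, `POPMAX_AF` and `INDEL` (flag), one sample column
#' per subject. Case/control labels are encoded in a `##SAMPLE_GROUPS`
#' header line (and recoverable from the `case_`/`ctrl_` id convention of
#' simulated cohorts), since plain VCF has no group field.
#'
#' @param x a [HomCohort-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readCohortVcf()] for the inverse.
#' @export
writeCohortVcf <- function(x, path) {
    stopifnot(is(x, "HomCohort"))
    con <- file(path, open = "wt")
    on.exit(close(con))
    grp <- as.character(x$group)
    hdr <- c(
        "##fileformat=VCFv4.2",
        "##source=homburden",
        '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
        '##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description="Consequence class: missense|nonsense|splice_junction|other">',
        '##INFO=<ID=CADD,Number=1,Type=Float,Description="CADD phred score">',
        '##INFO=<ID=POPMAX_AF,Number=1,Type=Float,Description="Maximum allele frequency across reference populations">',
        '##INFO=<ID=INDEL,Number=0,Type=Flag,Description="Insertion/deletion variant">',
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
        '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality (phred)">',
        '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Read depths for ref and alt alleles">',
        paste0("##SAMPLE_GROUPS=", paste(grp, collapse = ",")))
    if (nrow(x)) {
        contigs <- unique(as.character(GenomicRanges::seqnames(rowRanges(x))))
        hdr <- append(hdr, paste0("##contig=<ID=", contigs, ">"),
                      after = 2L)
    }
    writeLines(hdr, con)
    writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(x)),
                     collapse = "\t"), con)
    if (nrow(x) == 0) return(invisible(path))

    rd <- rowData(x)
    info <- sprintf("GENE=%s;CSQ_CLASS=%s;CADD=%s;POPMAX_AF=%s",
                    rd$gene, rd$csqClass,
                    format(rd$cadd, trim = TRUE, scientific = FALSE,
                           digits = 15),
                    format(rd$popmaxAF, trim = TRUE, scientific = FALSE,
                           digits = 15))
    info[rd$isIndel] <- paste0(info[rd$isIndel], ";INDEL")

    gt <- genotypes(x); gq <- genoQual(x)
    rdm <- refDepth(x); adm <- altDepth(x)
    gtStr <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow = nrow(gt))
    gtStr[is.na(gt)] <- "./."
    gqStr <- matrix(as.character(as.integer(gq)), nrow = nrow(gq))
    gqStr[is.na(gq)] <- "."
    adStr <- matrix(paste0(ifelse(is.na(rdm), ".", as.integer(rdm)), ",",
                           ifelse(is.na(adm), ".", as.integer(adm))),
                    nrow = nrow(rdm))
    cells <- matrix(paste(gtStr, gqStr, adStr, sep = ":"), nrow = nrow(gt))
    gr <- rowRanges(x)
    fixed <- paste(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr), names(gr),
                   rd$ref, rd$alt, ".", "PASS", info, "GT:GQ:AD",
                   sep = "\t")
    body <- paste(fixed, apply(cells, 1L, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(body, con)
    invisible(path)
}

#' Read a cohort from VCF
#'
#' Parses a VCF (via [VariantAnnotation::readVcf()]) carrying the dialect
#' written by [writeCohortVcf()]: `FORMAT GT:GQ:AD` plus the INFO keys
#' `GENE`, `CSQ_CLASS`, `CADD`, `POPMAX_AF`, `INDEL`. Missing FORMAT
#' fields are tolerated with a warning (the corresponding assay is `NA`
#' and downstream filters that need it report the data as unfilterable).
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param groups optional character vector of `"case"`/`"control"` labels,
#'   one per sample in file order. If `NULL`, labels are taken from the
#'   `##SAMPLE_GROUPS` header line, or failing that inferred from
#'   `case_`/`ctrl_` sample-id prefixes.
#' @return a [HomCohort-class].
#' @importFrom VariantAnnotation readVcf geno info header meta
#' @export
readCohortVcf <- function(path, groups = NULL) {
    vcf <- VariantAnnotation::readVcf(path)
    ids <- colnames(vcf)
    if (is.null(groups)) {
        hl <- readLines(path, n = 200L)
        gl <- grep("^##SAMPLE_GROUPS=", hl, value = TRUE)
        if (length(gl) == 1L) {
            groups <- strsplit(sub("^##SAMPLE_GROUPS=", "", gl[1L]),
                               ",", fixed = TRUE)[[1L]]
        } else {
            groups <- ifelse(startsWith(ids, "case"), "case",
                      ifelse(startsWith(ids, "ctrl") |
                             startsWith(ids, "control"), "control", NA))
            if (anyNA(groups))
                stop("cannot infer case/control labels; pass 'groups'")
        }
    }
    if (length(groups) != length(ids))
        stop("'groups' must have one label per sample")

    nv <- nrow(vcf); ns <- length(ids)
    gmat <- function(field, default = NA_real_) {
        g <- VariantAnnotation::geno(vcf)
        if (field %in% names(g)) return(g[[field]])
        warning("VCF lacks FORMAT field ", field,
                "; filling with NA (filters using it will be inert)")
        matrix(default, nv, ns)
    }
    gtRaw <- gmat("GT", NA_character_)
    gt <- matrix(NA_integer_, nv, ns)
    gt[gtRaw %in% c("0/0", "0|0")] <- 0L
    gt[gtRaw %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    gt[gtRaw %in% c("1/1", "1|1")] <- 2L
    gq <- gmat("GQ")
    storage.mode(gq) <- "double"
    adRaw <- gmat("AD")
    if (is.list(adRaw)) {
        pick <- function(k) matrix(vapply(adRaw, function(v) {
            if (length(v) >= k && !is.na(v[k])) as.double(v[k]) else NA_real_
        }, 0), nv, ns)
        rdm <- pick(1L); adm <- pick(2L)
    } else if (length(dim(adRaw)) == 3L) {
        rdm <- adRaw[, , 1L, drop = TRUE]; adm <- adRaw[, , 2L, drop = TRUE]
        dim(rdm) <- dim(adm) <- c(nv, ns)
    } else {
        rdm <- matrix(NA_real_, nv, ns); adm <- matrix(NA_real_, nv, ns)
    }

    inf <- VariantAnnotation::info(vcf)
    getInfo <- function(key, default) {
        if (key %in% colnames(inf)) {
            v <- inf[[key]]
            if (is(v, "List") || is.list(v))
                v <- vapply(v, function(z)
                    if (length(z)) z[1L] else default, default)
            v
        } else rep(default, nv)
    }
    gr <- SummarizedExperiment::rowRanges(vcf)
    variants <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        pos = GenomicRanges::start(gr),
        ref = as.character(VariantAnnotation::ref(vcf)),
        alt = vapply(as(VariantAnnotation::alt(vcf), "CharacterList"),
                     function(a) if (length(a)) a[1L] else "N", ""),
        gene = as.character(getInfo("GENE", NA_character_)),
        csqClass = as.character(getInfo("CSQ_CLASS", "other")),
        cadd = as.numeric(getInfo("CADD", NA_real_)),
        popmaxAF = as.numeric(getInfo("POPMAX_AF", NA_real_)),
        isIndel = as.logical(getInfo("INDEL", FALSE)),
        id = rownames(vcf))
    variants$isIndel[is.na(variants$isIndel)] <- FALSE
    HomCohort(gt, gq, rdm, adm, variants,
              data.frame(id = ids, group = groups))
}
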