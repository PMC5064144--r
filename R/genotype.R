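# Genotype handling: merged-VCF ingest with FILTER=PASS retention,
# minor-allele-count coding, per-amplicon summaries, and the universe of
# unique genotype profiles used for multiple-testing correction.

#' Ingest a merged multi-sample VCF as a minor-allele-count matrix
#'
#' Records with FILTER other than PASS are dropped; multi-allelic sites are
#' split into one biallelic record per ALT allele; GT fields are converted to
#' ALT-allele counts and then recoded so the count refers to the cohort minor
#' allele (cohort-wide frequency pooled over all samples; a 0.5 tie keeps ALT
#' as minor). Missing GT gives a missing entry.
#'
#' @param path VCF v4.2 file.
#' @param samples sample manifest: the ids to extract (all must be present);
#'   default all samples in the file.
#' @return list of class \code{genotype_matrix}: \code{geno} integer matrix
#'   (subjects x variants, 0/1/2/NA), \code{variants} metadata data frame
#'   (key, id, gene, chrom, pos, ref, alt, minor_is_alt, maf), and
#'   \code{samples}.
#' @export
ingest_vcf <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_m <- vcfR::getFIX(vcf)
  if (is.null(dim(fix_m)))          # single-record files come back as a vector
    fix_m <- matrix(fix_m, nrow = 1L, dimnames = list(NULL, names(fix_m)))
  fix <- as.data.frame(fix_m, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  vcf_samples <- colnames(gt)
  if (is.null(samples)) samples <- vcf_samples
  missing_s <- setdiff(samples, vcf_samples)
  if (length(missing_s))
    stop("manifest sample(s) absent from VCF: ", paste(missing_s, collapse = ", "))
  gt <- gt[, samples, drop = FALSE]
  info <- vcf@fix[, "INFO"]
  gene <- sub(".*GENE=([^;]+).*", "\\1", info)
  gene[!grepl("GENE=", info)] <- NA_character_

  pass <- which(!is.na(fix$FILTER) & fix$FILTER == "PASS")
  rows <- list()
  for (i in pass) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    alleles <- strsplit(gt[i, ], "[/|]")
    for (a in seq_along(alts)) {
      counts <- vapply(alleles, function(al) {
        if (length(al) == 0L || anyNA(al) || any(al == ".")) return(NA_integer_)
        sum(al == as.character(a))
      }, integer(1))
      rows[[length(rows) + 1L]] <- list(
        id = fix$ID[i], gene = gene[i], chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[a],
        counts = counts)
    }
  }
  if (!length(rows)) stop("no PASS records in ", path)
  geno <- do.call(cbind, lapply(rows, `[[`, "counts"))
  rownames(geno) <- samples
  meta <- do.call(rbind, lapply(rows, function(r)
    data.frame(key = paste(r$chrom, r$pos, r$ref, r$alt, sep = ":"),
               id = r$id, gene = r$gene, chrom = r$chrom, pos = r$pos,
               ref = r$ref, alt = r$alt, stringsAsFactors = FALSE)))
  # recode to cohort minor allele
  alt_freq <- colSums(geno, na.rm = TRUE) /
    (2 * colSums(!is.na(geno)))
  flip <- alt_freq > 0.5
  geno[, flip] <- 2L - geno[, flip, drop = FALSE]
  meta$minor_is_alt <- !flip
  meta$maf <- ifelse(flip, 1 - alt_freq, alt_freq)
  colnames(geno) <- ifelse(is.na(meta$id) | meta$id == ".", meta$key, meta$id)
  # disambiguate split multi-allelic records sharing an rsID
  dup <- duplicated(colnames(geno)) | duplicated(colnames(geno), fromLast = TRUE)
  colnames(geno)[dup] <- meta$key[dup]
  meta$name <- colnames(geno)
  structure(list(geno = geno, variants = meta, samples = samples),
            class = "genotype_matrix")
}

#' Join CADD deleteriousness annotation onto a genotype matrix
#'
#' @param gm a \code{genotype_matrix}.
#' @param cadd data frame with columns \code{id} and \code{cadd}.
#' @return the matrix with a \code{cadd} column added to its metadata.
#' @export
annotate_cadd <- function(gm, cadd) {
  stopifnot(inherits(gm, "genotype_matrix"),
            all(c("id", "cadd") %in% names(cadd)))
  gm$variants$cadd <- cadd$cadd[match(gm$variants$id, cadd$id)]
  gm
}

#' Per-amplicon variant counts and per-variant allele frequencies
#'
#' For each amplicon target region: the number of variants at which each
#' subject carries at least one minor allele. For each variant: the
#' minor-allele frequency, (sum of minor-allele counts) / (2 x subjects with
#' a called genotype).
#'
#' @param gm a \code{genotype_matrix}.
#' @param manifest amplicon manifest: \code{target_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive coordinates).
#' @return list: \code{per_subject} (subject x amplicon count matrix),
#'   \code{per_variant} (metadata plus \code{maf}, \code{amplicon};
#'   variants outside all amplicons are flagged \code{unassigned}).
#' @export
amplicon_summaries <- function(gm, manifest) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  amp <- rep(NA_character_, nrow(v))
  for (i in seq_len(nrow(manifest))) {
    hit <- v$chrom == manifest$chrom[i] & v$pos >= manifest$start[i] &
      v$pos <= manifest$end[i]
    amp[hit & is.na(amp)] <- manifest$target_id[i]
  }
  carrier <- !is.na(gm$geno) & gm$geno >= 1L
  ids <- unique(manifest$target_id)
  per_subject <- vapply(ids, function(a) {
    cols <- which(!is.na(amp) & amp == a)
    if (!length(cols)) return(integer(nrow(carrier)))
    as.integer(rowSums(carrier[, cols, drop = FALSE]))
  }, integer(nrow(gm$geno)))
  rownames(per_subject) <- rownames(gm$geno)
  pv <- v
  pv$amplicon <- amp
  pv$unassigned <- is.na(amp)
  pv$maf <- colSums(gm$geno, na.rm = TRUE) / (2 * colSums(!is.na(gm$geno)))
  list(per_subject = per_subject, per_variant = pv)
}

#' Build the unique-genotype-profile universe for one ethnic group
#'
#' Restricts the matrix to the group's subjects, drops monomorphic variants
#' (no variability in the number of minor alleles), and counts the distinct
#' remaining genotype column vectors. K, the number of unique profiles, is
#' the multiple-testing family size used by Bonferroni/BY adjustment.
#'
#' @param gm a \code{genotype_matrix} or a bare subjects x variants matrix.
#' @param subjects subject ids of the group (default: all rows).
#' @param label group label carried in the result.
#' @return list of class \code{profile_universe}: \code{K}, \code{profile}
#'   (named integer vector: variant -> profile id, NA for monomorphic
#'   variants), \code{subjects}, \code{label}.
#' @export
build_profile_universe <- function(gm, subjects = NULL, label = NA_character_) {
  M <- if (inherits(gm, "genotype_matrix")) gm$geno else as.matrix(gm)
  if (is.null(subjects)) subjects <- rownames(M)
  if (!length(subjects)) stop("at least one subject is required")
  M <- M[subjects, , drop = FALSE]
  keys <- apply(M, 2L, function(col) paste(col, collapse = ","))
  variable <- apply(M, 2L, function(col) {
    u <- unique(col[!is.na(col)]); length(u) > 1L
  })
  if (!any(variable))
    stop("all variants are monomorphic in this group; K undefined")
  prof <- rep(NA_integer_, ncol(M))
  names(prof) <- colnames(M)
  uk <- unique(keys[variable])
  prof[variable] <- match(keys[variable], uk)
  structure(list(K = length(uk), profile = prof,
                 subjects = subjects, label = label),
            class = "profile_universe")
}
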