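# A synthetic worked-example fixture: published-style genotype-group summary
# cells (mean, SD, n of the subject-level 19-h averaged BP response per
# number of minor alleles) expanded into subject-level response series whose
# group means and SDs match the cells exactly. The subject-level values are
# synthetic constructions consistent with the cells, not subject data.

#' Load the bundled genotype-group summary cells
#'
#' Group-level worked-example cells (per variant x #MA: group size, mean and
#' SD of the subject-level BP response averaged over 19 h) for the vigorous
#' and moderate exercise intensities in the African-American group.
#'
#' @return data frame: intensity, variant, gene, ethnicity, ma, n, sbp_mean,
#'   sbp_sd, dbp_mean, dbp_sd.
#' @export
load_group_cells <- function() {
  utils::read.delim(system.file("extdata", "synthetic_group_cells.tsv",
                                package = "pehscreen"),
                    stringsAsFactors = FALSE)
}

#' Expand summary cells into subject-level response series
#'
#' For each genotype group, constructs \code{n} subject-level values with
#' exactly the cell's mean and (sample) SD using a fixed centered unit-SD
#' score vector, then emits a flat 19-hour response series per subject; the
#' subject-level 19-h average therefore equals the constructed value and
#' \code{\link{genotype_group_summary}} reproduces the cells exactly.
#'
#' @param cells data frame as from \code{\link{load_group_cells}}.
#' @param variant variant id to expand.
#' @param intensity intensity to expand.
#' @param hours hour grid (default 1..19).
#' @return list: \code{responses} (subject, hour, sbp, dbp), \code{ma}
#'   (named minor-allele counts).
#' @export
expand_group_cells <- function(cells, variant, intensity, hours = 1:19) {
  cc <- cells[cells$variant == variant & cells$intensity == intensity, ,
              drop = FALSE]
  if (!nrow(cc)) stop("no cells for ", variant, " / ", intensity)
  rows <- list(); ma <- integer(0)
  for (i in seq_len(nrow(cc))) {
    n <- cc$n[i]
    z <- if (n > 1L) as.vector(scale(seq_len(n))) else 0
    sbp <- cc$sbp_mean[i] + (if (n > 1L) cc$sbp_sd[i] else 0) * z
    dbp <- cc$dbp_mean[i] + (if (n > 1L) cc$dbp_sd[i] else 0) * z
    for (s in seq_len(n)) {
      sid <- sprintf("%s_ma%d_%02d", variant, cc$ma[i], s)
      rows[[sid]] <- data.frame(subject = sid, hour = hours,
                                sbp = sbp[s], dbp = dbp[s],
                                stringsAsFactors = FALSE)
      ma[sid] <- cc$ma[i]
    }
  }
  list(responses = do.call(rbind, rows), ma = ma)
}

#' Worked-example genotype-group contrasts
#'
#' Convenience wrapper: expands the bundled cells for one variant and
#' returns the genotype-group summary, whose contrasts (mean at k minor
#' alleles minus mean at 0) reproduce the published in-text values.
#'
#' @param variant variant id present in the bundled cells.
#' @param intensity \code{"VIGOROUS"} or \code{"MODERATE"}.
#' @return as \code{\link{genotype_group_summary}}.
#' @export
worked_example_summary <- function(variant, intensity = "VIGOROUS") {
  cells <- load_group_cells()
  ex <- expand_group_cells(cells, variant, intensity)
  genotype_group_summary(ex$responses, ex$ma)
}
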