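#' Define the set of alleles segregating at the drive locus
#'
#' An allele set names the alleles at the target locus and records, for each,
#' the per-generation rate at which the homing drive converts it in drive
#' heterozygotes. The drive allele itself is never converted (susceptibility
#' 0); the wild-type allele is converted at the drive's conversion efficiency
#' `c`; a resistant allele is converted at the (lower) resistance level
#' `R <= c`, with `R = 0` meaning full immunity to homing.
#'
#' @param labels Character vector of allele names. The default three-allele
#'   locus (`drive`, `wild`, `resistant`) is what [drive_scenario()] uses.
#' @param susceptibility Numeric vector, one entry per allele, each in
#'   \[0, 1\]: conversion rate of the drive acting on that allele.
#' @param drive Name of the drive allele (must have susceptibility 0).
#' @param wild Name of the wild-type allele.
#'
#' @return An object of class `allele_set`: a list with elements `labels`,
#'   `susceptibility` (named), `drive` and `wild` (indices).
#' @examples
#' allele_set(susceptibility = c(0, 0.9, 0.2))
#' @export
allele_set <- function(labels = c("drive", "wild", "resistant"),
                       susceptibility,
                       drive = labels[1], wild = labels[2]) {
  if (!is.character(labels) || anyDuplicated(labels) || length(labels) < 2)
    stop("`labels` must be at least two distinct allele names", call. = FALSE)
  if (length(susceptibility) != length(labels))
    stop("`susceptibility` must have one entry per allele", call. = FALSE)
  if (any(!is.finite(susceptibility)) ||
      any(susceptibility < 0) || any(susceptibility > 1))
    stop("all susceptibilities must lie in [0, 1]", call. = FALSE)
  di <- match(drive, labels)
  wi <- match(wild, labels)
  if (is.na(di)) stop("drive allele '", drive, "' not among labels", call. = FALSE)
  if (is.na(wi) || wi == di)
    stop("wild-type allele must be a non-drive allele", call. = FALSE)
  if (susceptibility[di] != 0)
    stop("the drive allele cannot convert itself: susceptibility must be 0",
         call. = FALSE)
  structure(list(labels = labels,
                 susceptibility = stats::setNames(as.numeric(susceptibility),
                                                  labels),
                 drive = di, wild = wi),
            class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat("Allele set (", length(x$labels), " alleles)\n", sep = "")
  role <- rep("", length(x$labels))
  role[x$drive] <- "drive"
  role[x$wild] <- "wild-type"
  for (i in seq_along(x$labels))
    cat(sprintf("  %-10s susceptibility = %-6g %s\n",
                x$labels[i], x$susceptibility[i], role[i]))
  invisible(x)
}

## shared frequency / genotype validators ------------------------------------

check_freqs <- function(p, what = "allele frequencies", tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 2 || any(!is.finite(p)))
    stop(what, " must be a finite numeric vector of length >= 2", call. = FALSE)
  if (any(p < 0) || any(p > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(what, " must sum to 1 (got ", format(sum(p), digits = 12), ")",
         call. = FALSE)
  invisible(p)
}

check_genotypes <- function(G, tol = 1e-9) {
  if (!is.matrix(G) || nrow(G) != ncol(G) || any(!is.finite(G)))
    stop("genotype state must be a finite square matrix", call. = FALSE)
  if (any(G < 0))
    stop("genotype frequencies must be non-negative", call. = FALSE)
  if (max(abs(G - t(G))) > tol)
    stop("genotype state must be symmetric", call. = FALSE)
  if (abs(sum(G) - 1) > tol)
    stop("genotype mass must sum to 1 (got ", format(sum(G), digits = 12), ")",
         call. = FALSE)
  invisible(G)
}
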