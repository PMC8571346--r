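#' Technical coefficient matrix
#'
#' A = Z diag(X)^-1: column j holds the inputs required per unit gross
#' output of sector j. Sectors with zero output get a zero column (and must
#' have a zero transaction column, otherwise the table is inconsistent).
#'
#' @param mrio an `mrio_table`.
#' @return N x N coefficient matrix.
#' @export
technical_coefficients <- function(mrio) {
  X <- mrio$X
  zero <- X <= 0
  if (any(zero)) {
    bad <- zero & colSums(mrio$Z) > 0
    if (any(bad))
      stop("inconsistent table: zero output with non-zero input column at ",
           paste(names(X)[bad], collapse = ", "))
    warning("zero-output sectors get zero coefficient columns: ",
            paste(names(X)[zero], collapse = ", "))
  }
  Xs <- ifelse(zero, 1, X)
  A <- sweep(mrio$Z, 2, Xs, `/`)
  A[, zero] <- 0
  A
}

#' Leontief inverse (total requirements) matrix
#'
#' L = (I - A)^-1 exists for a productive economy (spectral radius of A
#' below one) and dominates the identity elementwise for non-negative A.
#'
#' @param A technical coefficient matrix.
#' @return N x N total-requirements matrix.
#' @export
leontief_inverse <- function(A) {
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("Leontief system divergent: spectral radius %.6f >= 1", rho))
  solve(diag(nrow(A)) - A)
}

#' Allocate regional crop and livestock NH3 totals to sectors
#'
#' Within a region, the crop total is split across crop-tagged sectors in
#' proportion to gross output (one emission intensity per category within
#' a region), likewise for livestock; non-agricultural sectors receive
#' zero. The split conserves the regional category totals exactly.
#'
#' @param category_totals data frame with columns region, crop, livestock
#'   (Gg per year).
#' @param mrio the `mrio_table` providing sector outputs.
#' @return a `sector_emissions` data frame.
#' @export
allocate_agricultural_emissions <- function(category_totals, mrio) {
  if (any(category_totals$crop < 0) || any(category_totals$livestock < 0))
    stop("category totals must be non-negative")
  idx <- mrio$index
  em <- numeric(nrow(idx))
  for (r in unique(idx$region)) {
    row <- category_totals[category_totals$region == r, ]
    if (nrow(row) == 0) next
    for (cat in c("crop", "livestock")) {
      i <- idx$region == r & idx$category == cat
      total <- row[[cat]]
      if (total == 0) next
      outsum <- sum(mrio$X[i])
      if (outsum <= 0)
        stop("region ", r, " has a positive ", cat,
             " total but zero output in that category")
      em[i] <- total * mrio$X[i] / outsum
    }
  }
  out <- data.frame(idx, output = unname(mrio$X), emissions = em,
                    stringsAsFactors = FALSE)
  class(out) <- c("sector_emissions", "data.frame")
  out
}

#' Sectoral NH3 emission intensity vector
#'
#' D_i = emissions_i / X_i for agricultural (crop or livestock) sectors and
#' exactly zero for all others; any positive emission recorded on a
#' non-agricultural sector is rejected.
#'
#' @param emissions a `sector_emissions` table aligned with `mrio`.
#' @param mrio the `mrio_table`.
#' @param category optionally restrict to `"crop"` or `"livestock"`
#'   (intensities outside the category are zeroed).
#' @return named N-vector of intensities (Gg per monetary unit).
#' @export
emission_intensities <- function(emissions, mrio, category = NULL) {
  idx <- mrio$index
  if (!identical(emissions$region, idx$region) ||
      !identical(emissions$sector, idx$sector))
    stop("emissions table does not align with the MRIO index")
  if (any(emissions$emissions[idx$category == "other"] > 0))
    stop("non-agricultural sectors must carry zero emissions")
  keep <- if (is.null(category)) idx$category %in% c("crop", "livestock")
          else idx$category %in% category
  bad <- keep & emissions$emissions > 0 & mrio$X <= 0
  if (any(bad))
    stop("zero output with positive emissions at ",
         paste(names(mrio$X)[bad], collapse = ", "))
  D <- ifelse(keep & mrio$X > 0, emissions$emissions / mrio$X, 0)
  names(D) <- names(mrio$X)
  D
}

#' Embodied emission flow matrix and country aggregation
#'
#' C = diag(D) L F_hat, where F_hat holds each consuming region's final
#' demand vector in its destination column, so C\[i, t\] is the NH3
#' emitted by producing sector i embodied in the final consumption of
#' economy t (direct plus all upstream supply-chain requirements). The
#' country matrix T aggregates the producing sectors of each economy:
#' T\[s, t\] is the emission produced in economy s for consumption in t.
#'
#' @param D intensity vector from [emission_intensities()].
#' @param L Leontief inverse.
#' @param mrio the `mrio_table` (provides destination-resolved final
#'   demand and the region index).
#' @return list with sector-level `C` (N producing sectors x n consuming
#'   regions) and country-level `T` (n x n), both in Gg.
#' @export
embodied_flow_matrix <- function(D, L, mrio) {
  if (any(mrio$F < 0)) stop("negative final demand rejected")
  idx <- mrio$index
  n <- length(mrio$regions)
  C <- D * (L %*% mrio$F)                  # N x n
  dimnames(C) <- list(names(mrio$X), mrio$regions)
  rblock <- match(idx$region, mrio$regions)
  Tmat <- rowsum(C, group = rblock, reorder = TRUE)
  dimnames(Tmat) <- list(mrio$regions, mrio$regions)
  list(C = C, T = Tmat)
}

#' Production/consumption-based accounts from a country flow matrix
#'
#' EEE (emissions embodied in exports), EEI (in imports), their balance
#' EEB = EEI - EEE, production-based PBE (row sums) and consumption-based
#' CBE (column sums). EEB also equals CBE - PBE, and sums to zero over all
#' economies.
#'
#' @param T country-level embodied flow matrix (Gg).
#' @return data frame with columns region, PBE, CBE, EEI, EEE, EEB.
#' @export
trade_accounts <- function(T) {
  if (!is.matrix(T) || nrow(T) != ncol(T) || any(T < 0))
    stop("T must be a square non-negative matrix")
  off <- T
  diag(off) <- 0
  data.frame(region = rownames(T),
             PBE = rowSums(T), CBE = colSums(T),
             EEI = colSums(off), EEE = rowSums(off),
             EEB = colSums(off) - rowSums(off),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export-related fraction of each economy's agricultural emissions
#'
#' fraction_s = EEE_s / PBE_s, the share of domestically produced
#' agricultural NH3 embodied in foreign final consumption. The fraction is
#' applied uniformly to all of the economy's gridded agricultural NH3 in
#' the dispersion surrogate. Economies with zero production-based
#' emissions get fraction zero.
#'
#' @param accounts output of [trade_accounts()].
#' @return named per-region fraction in \[0, 1\].
#' @export
export_emission_fraction <- function(accounts) {
  if (any(accounts$PBE <= 0 & accounts$EEE > 1e-12))
    stop("inconsistent accounts: exports without production")
  f <- ifelse(accounts$PBE > 0, accounts$EEE / accounts$PBE, 0)
  names(f) <- accounts$region
  if (any(f < -1e-12 | f > 1 + 1e-12)) stop("export fraction outside [0, 1]")
  pmin(pmax(f, 0), 1)
}

#' Full embodied-emission accounting for a synthetic world
#'
#' Convenience chain: intensities, Leontief inverse, flow matrices (total
#' and per category) and trade accounts.
#'
#' @param world a `synthetic_world`.
#' @return list with `D`, `L`, `flows` (total), `flows_crop`,
#'   `flows_livestock`, `accounts`, `export_fraction` and per-category
#'   export fractions.
#' @export
mrio_accounts <- function(world) {
  mrio <- world$mrio
  A <- technical_coefficients(mrio)
  L <- leontief_inverse(A)
  D <- emission_intensities(world$emissions, mrio)
  D_crop <- emission_intensities(world$emissions, mrio, category = "crop")
  D_liv <- emission_intensities(world$emissions, mrio, category = "livestock")
  flows <- embodied_flow_matrix(D, L, mrio)
  flows_crop <- embodied_flow_matrix(D_crop, L, mrio)
  flows_liv <- embodied_flow_matrix(D_liv, L, mrio)
  accounts <- trade_accounts(flows$T)
  list(A = A, L = L, D = D,
       flows = flows, flows_crop = flows_crop, flows_livestock = flows_liv,
       accounts = accounts,
       accounts_crop = trade_accounts(flows_crop$T),
       accounts_livestock = trade_accounts(flows_liv$T),
       export_fraction = export_emission_fraction(accounts))
}
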