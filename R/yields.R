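#' Default electron ledger (degrees of reduction)
#'
#' Available electrons per mole for the metabolites of the syngas
#' co-fermentation system: CO and H2 carry 2 e- per mol, acetate 8,
#' succinate 14, hexanoate 32. Further compounds follow from the degree of
#' reduction of their formula (4C + H - 2O for CHO compounds): ethanol 12,
#' butyrate 20, butanol 24, hexanol 36, formate 2.
#'
#' @param extra named integer vector of additional/overriding electron counts.
#' @param gas_consumption_fraction fraction of the fed gas assumed consumed
#'   when a gas discount is applied (default 0.9).
#' @return object of class \code{electron_ledger}.
#' @export
electron_ledger <- function(extra = NULL, gas_consumption_fraction = 0.9) {
  e <- c(co = 2, h2 = 2, ac = 8, succ = 14, hexa = 32,
         etoh = 12, buty = 20, btoh = 24, hxoh = 36, form = 2)
  if (!is.null(extra)) e[names(extra)] <- extra
  if (any(e <= 0)) stop("electron counts must be > 0", call. = FALSE)
  if (gas_consumption_fraction <= 0 || gas_consumption_fraction > 1) {
    stop("gas_consumption_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(list(electrons_per_mol = e,
                 gas_consumption_fraction = gas_consumption_fraction),
            class = "electron_ledger")
}

#' Default carbon ledger
#'
#' Carbon atoms per mole: CO 1, CO2 1, acetate/ethanol 2, succinate/butyrate/
#' butanol 4, hexanoate/hexanol 6, formate 1.
#'
#' @param extra named integer vector of additional/overriding carbon counts.
#' @return object of class \code{carbon_ledger}.
#' @export
carbon_ledger <- function(extra = NULL) {
  cc <- c(co = 1, co2 = 1, ac = 2, etoh = 2, succ = 4, buty = 4, btoh = 4,
          hexa = 6, hxoh = 6, form = 1)
  if (!is.null(extra)) cc[names(extra)] <- extra
  if (any(cc <= 0)) stop("carbon counts must be > 0", call. = FALSE)
  structure(list(carbons_per_mol = cc), class = "carbon_ledger")
}

#' Electron yield of a fermentation product
#'
#' Fraction of the electrons entering the system (as substrates) that end up
#' in the named product:
#' \code{yield = rate_p * e(p) / sum_i rate_i * e(i) * g_i}, where
#' \code{g_i} is the ledger's gas-consumption fraction for substrates flagged
#' as gases (when \code{discount_gas = TRUE}) and 1 otherwise. With
#' \code{discount_gas = FALSE} the undiscounted formula is used exactly.
#'
#' @param substrate_rates named numeric vector of substrate feed rates
#'   (mmol l-1 h-1, non-negative).
#' @param product metabolite name of the product.
#' @param product_rate product formation rate (mmol l-1 h-1).
#' @param ledger an \code{\link{electron_ledger}}.
#' @param gas_metabolites names of substrates that are gases.
#' @param discount_gas apply the ledger's gas-consumption fraction to gas
#'   substrates.
#' @return electron yield (dimensionless fraction).
#' @export
electron_yield <- function(substrate_rates, product, product_rate,
                           ledger = electron_ledger(),
                           gas_metabolites = c("co", "h2"),
                           discount_gas = FALSE) {
  e <- ledger$electrons_per_mol
  missing <- setdiff(c(names(substrate_rates), product), names(e))
  if (length(missing)) {
    stop("metabolite(s) missing from electron ledger: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(substrate_rates < 0) || product_rate < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  g <- ifelse(names(substrate_rates) %in% gas_metabolites & discount_gas,
              ledger$gas_consumption_fraction, 1)
  denom <- sum(substrate_rates * e[names(substrate_rates)] * g)
  if (denom <= 0) stop("zero electron input", call. = FALSE)
  unname(product_rate * e[[product]] / denom)
}

#' Carbon-normalised product yield
#'
#' Product formation rate divided by total substrate carbon feed:
#' \code{product_rate / sum_i feed_i * C(i)}, in mmol of product per C-mmol
#' of substrate.
#'
#' @param product_rate product formation rate (mmol l-1 h-1).
#' @param feeds named numeric vector of substrate feed rates.
#' @param ledger a \code{\link{carbon_ledger}}.
#' @return yield in mmol product per C-mmol substrate.
#' @export
carbon_normalized_yield <- function(product_rate, feeds,
                                    ledger = carbon_ledger()) {
  if (!length(feeds)) stop("feeds must be nonempty", call. = FALSE)
  cc <- ledger$carbons_per_mol
  missing <- setdiff(names(feeds), names(cc))
  if (length(missing)) {
    stop("metabolite(s) missing from carbon ledger: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  denom <- sum(feeds * cc[names(feeds)])
  if (denom <= 0) stop("zero carbon input", call. = FALSE)
  unname(product_rate / denom)
}

#' Tabulate electron yields for a set of scenarios
#'
#' Convenience wrapper producing a yield table (one row per scenario) in the
#' style commonly used to compare fermentation studies: substrate rates, the
#' product rate, and the electron yield rounded to two decimals.
#'
#' @param rows list of lists with fields \code{label}, \code{substrates}
#'   (named rates), \code{product}, \code{product_rate}, and optional
#'   \code{discount_gas}.
#' @param ledger an \code{\link{electron_ledger}}.
#' @return data.frame with columns \code{label}, \code{substrates},
#'   \code{product_rate}, \code{electron_yield}.
#' @export
yield_report <- function(rows, ledger = electron_ledger()) {
  do.call(rbind, lapply(rows, function(r) {
    y <- electron_yield(r$substrates, r$product, r$product_rate, ledger,
                        discount_gas = isTRUE(r$discount_gas))
    data.frame(
      label = r$label,
      substrates = paste(sprintf("%s=%.3g", names(r$substrates),
                                 r$substrates), collapse = ", "),
      product_rate = r$product_rate,
      electron_yield = round(y, 2),
      stringsAsFactors = FALSE)
  }))
}
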