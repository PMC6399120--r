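#' Genetic inheritance models
#'
#' The five standard single-SNP codings of an effect-allele dosage
#' `d` in `{0, 1, 2}` for regression:
#' \describe{
#'   \item{dominant}{carrier indicator, `d >= 1`}
#'   \item{recessive}{homozygote indicator, `d == 2`}
#'   \item{overdominant}{heterozygote indicator, `d == 1`}
#'   \item{additive}{allele count, `d`}
#'   \item{codominant}{two indicators (heterozygote, effect homozygote), 2 df}
#' }
#' @format Character vector of the five model names, in the canonical
#'   tie-break order used throughout the package.
#' @export
inheritance_models <- c("dominant", "recessive", "overdominant",
                        "additive", "codominant")

#' Encode a dosage vector under an inheritance model
#'
#' @param dosage Integer vector of effect-allele dosages (`NA` allowed and
#'   propagated).
#' @param model One of [inheritance_models].
#' @return A numeric matrix with one column (two for codominant) named
#'   after the model; rows with missing dosage are `NA` throughout.
#' @export
#' @examples
#' encode_genotype(c(0, 1, 2, NA), "dominant")
encode_genotype <- function(dosage, model = inheritance_models) {
  model <- arg_match(model)
  d <- as.numeric(dosage)
  switch(model,
    dominant = cbind(dominant = as.numeric(d >= 1)),
    recessive = cbind(recessive = as.numeric(d == 2)),
    overdominant = cbind(overdominant = as.numeric(d == 1)),
    additive = cbind(additive = d),
    codominant = cbind(codominant_het = as.numeric(d == 1),
                       codominant_hom = as.numeric(d == 2))
  )
}

# Degrees of freedom contributed by each model's SNP term(s).
model_df <- function(model) if (model == "codominant") 2L else 1L
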