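# Host-distribution comparison for carrier strains and subgroup
# carrier-enrichment probabilities.

#' Compare carrier host distribution against the reference
#'
#' Pearson chi-square test of the carrier strains' host counts against
#' expectations proportional to the reference (all-strain) host
#' distribution, scaled to the carrier total. Categories with expected
#' count below 1 are pooled into `"other"` before the test. The result is
#' invariant to category order.
#'
#' @param reference_counts named integer vector: strains per host across
#'   all analysed strains.
#' @param carrier_counts named integer vector: carrier strains per host
#'   (categories are matched by name; absent categories count 0).
#' @return A list with `statistic`, `df`, `p_value`, and the pooled
#'   `observed`/`expected` tables.
#' @examples
#' compareHostDistributions(c(human = 30, turkey = 30),
#'                          c(human = 5, turkey = 25))
#' @export
compareHostDistributions <- function(reference_counts, carrier_counts) {
  if (is.null(names(reference_counts)))
    stop("reference_counts must be named by host category")
  cats <- names(reference_counts)
  carr <- stats::setNames(rep(0, length(cats)), cats)
  carr[intersect(names(carrier_counts), cats)] <-
    carrier_counts[intersect(names(carrier_counts), cats)]
  if (any(carr > reference_counts))
    stop("carrier counts exceed reference counts for: ",
         paste(cats[carr > reference_counts], collapse = ", "))
  if (length(cats) < 2L) stop("need at least 2 host categories")
  n_car <- sum(carr)
  if (n_car == 0) stop("no carrier strains")
  expected <- reference_counts / sum(reference_counts) * n_car
  ## pool categories with expected < 1 into "other"
  pool <- expected < 1
  if (any(pool)) {
    obs <- c(carr[!pool], other = sum(carr[pool]))
    exp_ <- c(expected[!pool], other = sum(expected[pool]))
  } else {
    obs <- carr
    exp_ <- expected
  }
  if (length(obs) < 2L)
    stop("a single category remains after pooling; test undefined")
  stat <- sum((obs - exp_)^2 / exp_)
  df <- length(obs) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = obs, expected = exp_)
}

#' Carrier enrichment within a strain subgroup
#'
#' Probability that a chance assignment of the `k` carrier strains within
#' a uniform subgroup of `n` strains places at least the observed number
#' in the focal host category of size `m` -- the upper hypergeometric
#' tail. When every carrier falls in the category this reduces to the
#' closed form `choose(m, k) / choose(n, k)`. A seeded permutation
#' estimate (default 1e5 draws) is available as a cross-check and agrees
#' with the exact tail within Monte-Carlo error.
#'
#' @param group character vector of strain ids in the subgroup.
#' @param carriers subset of `group`: the carrier strains.
#' @param category_members subset of `group`: strains in the focal host
#'   category.
#' @param method `"hypergeometric"` (exact tail) or `"permutation"`.
#' @param n_perm number of permutation draws.
#' @param seed RNG seed for the permutation method.
#' @return A list with `group_size`, `carriers_in_group`,
#'   `category_size`, `carriers_in_category`, `p_chance`, `method`, and
#'   for permutations the Monte-Carlo standard error `mc_se`.
#' @examples
#' g <- paste0("s", 1:10)
#' subgroupEnrichment(g, g[1:3], g[1:5])$p_chance  # C(5,3)/C(10,3)
#' @export
subgroupEnrichment <- function(group, carriers, category_members,
                               method = c("hypergeometric",
                                          "permutation"),
                               n_perm = 1e5, seed = 1L) {
  method <- match.arg(method)
  if (!all(carriers %in% group))
    stop("carriers must be a subset of the group")
  n <- length(group)
  k <- length(carriers)
  m <- sum(category_members %in% group)
  x <- sum(carriers %in% category_members)
  if (k == 0L) stop("no carriers in group")
  if (method == "hypergeometric") {
    ## P(X >= x), X ~ Hypergeometric(m in-category, n - m out, k draws)
    p <- stats::phyper(x - 1L, m, n - m, k, lower.tail = FALSE)
    mc_se <- NA_real_
  } else {
    draws <- .withSeed(seed, {
      vapply(seq_len(n_perm), function(i)
        sum(sample.int(n, k) <= m), 0L)
    })
    p <- mean(draws >= x)
    mc_se <- sqrt(p * (1 - p) / n_perm)
  }
  list(group_size = n, carriers_in_group = k, category_size = m,
       carriers_in_category = x, p_chance = p, method = method,
       mc_se = mc_se)
}

#' Host-association report for one homologue
#'
#' Convenience wrapper: builds the reference and carrier host
#' distributions for a homologue's carrier strains from the metadata
#' roster, runs [compareHostDistributions()], and returns a
#' machine-readable report. Strains with missing host are dropped from
#' both distributions. An optional synonym map normalises host labels
#' before counting; otherwise labels are used verbatim.
#'
#' @param carrier_strains character vector of carrier strain ids.
#' @param metadata roster `data.frame` from [readMetadata()].
#' @param synonyms optional named character vector mapping raw host
#'   labels to normalised ones.
#' @return A list with the two count tables and the chi-square result.
#' @export
hostAssociationReport <- function(carrier_strains, metadata,
                                  synonyms = NULL) {
  md <- metadata[!is.na(metadata$host), , drop = FALSE]
  host <- md$host
  if (!is.null(synonyms)) {
    mapped <- !is.na(synonyms[host])
    host[mapped] <- synonyms[host[mapped]]
  }
  ref <- table(host)
  carr <- table(host[md$strain_id %in% carrier_strains])
  ref_v <- stats::setNames(as.integer(ref), names(ref))
  carr_v <- stats::setNames(as.integer(carr), names(carr))
  test <- compareHostDistributions(ref_v, carr_v)
  list(reference_counts = ref_v, carrier_counts = carr_v,
       chi_square = test)
}

## Evaluate an expression under a temporary RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
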