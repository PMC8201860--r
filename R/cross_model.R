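# Mendelian model over sodium-channel haplotypes with a silencing modifier.
#
# Haplotype alphabet: S = wild-type, expressed, susceptible; R = resistance
# haplotype (kdr + skdr), expressed; M = wild-type haplotype silenced by an
# intragenic transposon insertion (not expressed; M/M is lethal because no
# functional channel is produced).  Phenotype rule: a genotype is nonviable
# when neither haplotype is expressed, resistant when viable and every
# expressed haplotype confers resistance (resistance is recessive in the
# sense that one expressed susceptible haplotype suffices for
# susceptibility), susceptible otherwise.

#' Default haplotype alphabet
#'
#' `S`, `R`, `M` as above, plus `R_L`: a haplotype carrying the alternative
#' super-kdr form (M918L analogue), inferred to confer resistance when
#' monoallelically expressed but not confirmed by bioassay.
#'
#' @return data.frame with columns name, expressed, resistance_conferring,
#'   inferred.
#' @export
default_haplotypes <- function() {
  data.frame(
    name = c("S", "R", "M", "R_L"),
    expressed = c(TRUE, TRUE, FALSE, TRUE),
    resistance_conferring = c(FALSE, TRUE, FALSE, TRUE),
    inferred = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Define a haplotype alphabet
#'
#' @param name haplotype names.
#' @param expressed logical: is the haplotype transcribed into functional
#'   channel?
#' @param resistance_conferring logical: does its product resist the
#'   insecticide?
#' @return data.frame usable as the `alphabet` argument of [phenotype()]
#'   and [cross()].
#' @export
haplotype_alphabet <- function(name, expressed, resistance_conferring) {
  stopifnot(length(name) == length(expressed),
            length(name) == length(resistance_conferring))
  data.frame(name = name, expressed = expressed,
             resistance_conferring = resistance_conferring,
             inferred = FALSE, stringsAsFactors = FALSE)
}

parse_genotype <- function(genotype) {
  if (length(genotype) == 1L) genotype <- strsplit(genotype, "/")[[1]]
  if (length(genotype) != 2L) stop("a genotype is a pair of haplotypes")
  genotype
}

#' Phenotype of a genotype
#'
#' @param genotype haplotype pair, as `"M/R"` or `c("M", "R")` (unordered).
#' @param alphabet haplotype alphabet (see [default_haplotypes()]).
#' @return `"resistant"`, `"susceptible"` or `"nonviable"`.
#' @examples
#' phenotype("S/R")   # resistance is recessive
#' phenotype("M/R")   # silenced wild-type allele unmasks resistance
#' phenotype("M/M")   # no expressed channel
#' @export
phenotype <- function(genotype, alphabet = default_haplotypes()) {
  g <- parse_genotype(genotype)
  unknown <- setdiff(g, alphabet$name)
  if (length(unknown)) stop("unknown haplotype(s): ",
                            paste(unknown, collapse = ", "))
  h <- alphabet[match(g, alphabet$name), ]
  if (!any(h$expressed)) return("nonviable")
  if (all(h$resistance_conferring[h$expressed])) "resistant" else "susceptible"
}

#' Enumerate progeny of a cross
#'
#' Enumerates the four equiprobable gamete pairs of two parents and
#' aggregates progeny genotypes and phenotypes.
#'
#' @param parent1,parent2 genotypes as in [phenotype()]; both must be
#'   viable.
#' @param alphabet haplotype alphabet.
#' @return a `cross_result`: list with `progeny` (data.frame genotype,
#'   probability, phenotype), `percent_resistant`, `percent_susceptible`,
#'   `percent_nonviable`, `percent_resistant_among_viable`.
#' @examples
#' cross("M/R", "S/R")$percent_resistant   # 50
#' cross("M/R", "M/R")$percent_nonviable   # 25
#' @export
cross <- function(parent1, parent2, alphabet = default_haplotypes()) {
  p1 <- parse_genotype(parent1)
  p2 <- parse_genotype(parent2)
  if (phenotype(p1, alphabet) == "nonviable" ||
      phenotype(p2, alphabet) == "nonviable") {
    stop("nonviable parent")
  }
  combos <- expand.grid(g1 = p1, g2 = p2, stringsAsFactors = FALSE)
  key <- apply(combos, 1, function(g) paste(sort(g), collapse = "/"))
  tab <- table(key) / 4
  progeny <- data.frame(genotype = names(tab),
                        probability = as.numeric(tab),
                        stringsAsFactors = FALSE)
  progeny$phenotype <- vapply(progeny$genotype, phenotype, character(1),
                              alphabet = alphabet)
  pct <- function(ph) 100 * sum(progeny$probability[progeny$phenotype == ph])
  res <- pct("resistant"); sus <- pct("susceptible"); nv <- pct("nonviable")
  structure(list(progeny = progeny,
                 percent_resistant = res,
                 percent_susceptible = sus,
                 percent_nonviable = nv,
                 percent_resistant_among_viable =
                   if (nv < 100) 100 * res / (res + sus) else NA_real_),
            class = "cross_result")
}

#' @export
print.cross_result <- function(x, ...) {
  cat("Progeny of cross:\n")
  for (i in seq_len(nrow(x$progeny))) {
    cat(sprintf("  %-6s %5.1f%%  %s\n", x$progeny$genotype[i],
                100 * x$progeny$probability[i], x$progeny$phenotype[i]))
  }
  cat(sprintf("resistant %.0f%% | susceptible %.0f%% | nonviable %.0f%%\n",
              x$percent_resistant, x$percent_susceptible,
              x$percent_nonviable))
  invisible(x)
}

#' Summarise a field screen for the insertion allele
#'
#' @param genotype_table data.frame with columns `clone`, `mule` (logical
#'   or "yes"/"no": insertion present) and optionally `skdr` (e.g. "M918T",
#'   "M918L") for stratification of carriers.
#' @return a `screen_summary` list: `n_clones`, `n_positive`,
#'   `prevalence_pct` (one decimal; 0 with `undefined = TRUE` for an empty
#'   table), `by_skdr` (table of skdr forms among carriers), `n_excluded`.
#' @examples
#' tbl <- data.frame(clone = paste0("c", 1:148),
#'                   mule = rep(c(TRUE, FALSE), c(8, 140)))
#' screen_summary(tbl)$prevalence_pct
#' @export
screen_summary <- function(genotype_table) {
  tbl <- genotype_table
  if (!"mule" %in% names(tbl)) stop("genotype table must have a 'mule' column")
  mule <- tbl$mule
  if (!is.logical(mule)) {
    mule <- tolower(as.character(mule))
    mule <- ifelse(mule %in% c("yes", "y", "true", "1"), TRUE,
                   ifelse(mule %in% c("no", "n", "false", "0"), FALSE, NA))
  }
  bad <- is.na(mule)
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable insertion status excluded")
  }
  tbl <- tbl[!bad, , drop = FALSE]
  mule <- mule[!bad]
  n <- nrow(tbl)
  np <- sum(mule)
  by_skdr <- if ("skdr" %in% names(tbl) && np > 0) {
    table(tbl$skdr[mule])
  } else NULL
  structure(list(n_clones = n, n_positive = np,
                 prevalence_pct = if (n > 0) round1(100 * np / n) else 0,
                 undefined = n == 0, by_skdr = by_skdr,
                 n_excluded = sum(bad)),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  if (x$undefined) {
    cat("Empty screen table: prevalence undefined (reported as 0)\n")
    return(invisible(x))
  }
  cat(sprintf("Insertion allele observed in %d/%d clones (%.1f%%)\n",
              x$n_positive, x$n_clones, x$prevalence_pct))
  if (!is.null(x$by_skdr)) {
    for (nm in names(x$by_skdr)) {
      cat(sprintf("  with %s: %d\n", nm, x$by_skdr[[nm]]))
    }
  }
  invisible(x)
}
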