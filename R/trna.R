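#' Read a tRNA gene table (GtRNAdb-style TSV or FASTA)
#'
#' TSV columns: `organism`, `isotype`, `anticodon`, `score`, `sequence`
#' (optional `secondary_structure`). The FASTA alternative encodes the same
#' fields in the header as `id organism=.. isotype=.. anticodon=.. score=..`.
#' Thymine is normalised to uracil.
#'
#' @param path input file.
#' @param format `"tsv"` or `"fasta"`.
#' @return data.frame with columns `organism`, `isotype`, `anticodon`,
#'   `score`, `sequence` (and `secondary_structure` if present).
#' @export
readTRNATable <- function(path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("organism", "isotype", "anticodon", "score", "sequence")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("tRNA table schema error: missing column(s) ",
           paste(miss, collapse = ", "))
  } else {
    ss <- Biostrings::readBStringSet(path)
    hdr <- names(ss)
    getfield <- function(key) {
      v <- sub(paste0(".*", key, "=(\\S+).*"), "\\1", hdr)
      ifelse(grepl(paste0(key, "="), hdr), v, NA_character_)
    }
    tab <- data.frame(
      organism = gsub("_", " ", getfield("organism")),
      isotype = getfield("isotype"),
      anticodon = getfield("anticodon"),
      score = as.numeric(getfield("score")),
      sequence = as.character(ss),
      stringsAsFactors = FALSE, row.names = NULL)
    if (anyNA(tab$organism) || anyNA(tab$isotype) || anyNA(tab$score))
      stop("tRNA FASTA schema error: headers must carry organism=, ",
           "isotype=, anticodon=, score=")
  }
  tab$sequence <- chartr("tT", "uU", tab$sequence)
  tab$sequence <- toupper(tab$sequence)
  tab
}

#' Filter tRNA genes by tRNAscan-SE score
#'
#' Strictly-greater filter (score > threshold), the criterion used to admit
#' database gene models into the enrichment survey.
#'
#' @param genes data.frame as from [readTRNATable()].
#' @param threshold bits; default 50.
#' @return the filtered data.frame.
#' @export
filterByScore <- function(genes, threshold = 50) {
  stopifnot(length(threshold) == 1, !is.na(threshold))
  genes[genes$score > threshold, , drop = FALSE]
}

#' Acceptor-stem base pairs of a tRNA gene sequence
#'
#' Numbers the mature gene on the canonical 1-72 scheme: a terminal CCA (if
#' present) is stripped, the final remaining base is the discriminator, and
#' 5' position i pairs with 3' position L - i for i = 1..7 (L = length
#' including the discriminator), so pair 4 is the 4:69 position of a
#' canonical 76-nt tRNA. An optional dot-bracket secondary structure, when
#' supplied, overrides the positional pairing for the first seven 5' paired
#' positions.
#'
#' @param sequence nucleotide string (A/C/G/U; T tolerated), length >= 60.
#' @param secondary_structure optional dot-bracket string of equal length.
#' @return data.frame with 7 rows: `pair_index`, `five_prime_base`,
#'   `three_prime_base`, `five_prime_pos`, `three_prime_pos`.
#' @examples
#' g <- genTRNASet(c(Thr = 1), wobble_prob = c(Thr = 1), seed = 1)
#' acceptorStemPairs(g$sequence[1])[4, ]  # the G4:U69 pair
#' @export
acceptorStemPairs <- function(sequence, secondary_structure = NULL) {
  s <- chartr("tT", "uU", toupper(sequence))
  if (grepl("CCA$", s)) s <- substr(s, 1, nchar(s) - 3)
  L <- nchar(s)
  if (L < 60) stop("sequence too short for acceptor-stem numbering (< 60 nt)")
  base <- strsplit(s, "")[[1]]
  if (!is.null(secondary_structure) && nzchar(secondary_structure)) {
    ss <- strsplit(secondary_structure, "")[[1]][seq_len(L)]
    partner <- .pairFromDotBracket(ss)
    fp <- which(ss %in% c("(", "<", "["))[1:7]
    tp <- partner[fp]
  } else {
    fp <- 1:7
    tp <- L - fp
  }
  data.frame(
    pair_index = 1:7,
    five_prime_base = base[fp],
    three_prime_base = base[tp],
    five_prime_pos = fp,
    three_prime_pos = tp,
    stringsAsFactors = FALSE)
}

.pairFromDotBracket <- function(ss) {
  partner <- rep(NA_integer_, length(ss))
  stack <- integer(0)
  for (i in seq_along(ss)) {
    if (ss[i] %in% c("(", "<", "[")) stack <- c(stack, i)
    else if (ss[i] %in% c(")", ">", "]")) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  partner
}

#' Wobble-pair call at an acceptor-stem position
#'
#' Direction matters: `is_G4U69` requires G on the 5' strand and U on the
#' 3' strand at pair 4; the reversed U:G pair is reported separately.
#'
#' @param stem data.frame from [acceptorStemPairs()].
#' @param pair_index 1-7 (default 4, the position misread by eukaryotic
#'   AlaRS).
#' @return list with `pair_index`, `bases`, `is_G4U69`, `is_U4G69`.
#' @export
detectWobble <- function(stem, pair_index = 4L) {
  stopifnot(pair_index %in% 1:7)
  row <- stem[stem$pair_index == pair_index, ]
  gu <- row$five_prime_base == "G" && row$three_prime_base == "U"
  ug <- row$five_prime_base == "U" && row$three_prime_base == "G"
  list(pair_index = as.integer(pair_index),
       bases = c(row$five_prime_base, row$three_prime_base),
       is_G4U69 = gu && pair_index == 4L,
       is_U4G69 = ug && pair_index == 4L)
}

#' Per-organism G4:U69 enrichment for an isotype
#'
#' Counts, per organism, how many genes of the given isotype carry the
#' G4:U69 wobble pair, as a percentage of that organism's genes of the
#' isotype. Genes are expected to be pre-filtered by score; organisms with
#' zero genes of the isotype are omitted with a warning. Each gene copy
#' counts once (isodecoder duplicates are not collapsed).
#'
#' @param genes data.frame as from [readTRNATable()].
#' @param isotype isotype to survey (e.g. `"Thr"`).
#' @return data.frame with columns `organism`, `isotype`, `n_total`,
#'   `n_wobble`, `fraction` (percent).
#' @export
wobbleEnrichment <- function(genes, isotype = "Thr") {
  sub <- genes[genes$isotype == isotype, , drop = FALSE]
  orgs <- unique(genes$organism)
  missing <- setdiff(orgs, unique(sub$organism))
  if (length(missing))
    warning("no ", isotype, " genes for: ", paste(missing, collapse = ", "),
            " (rows omitted)")
  if (!nrow(sub))
    return(data.frame(organism = character(0), isotype = character(0),
                      n_total = integer(0), n_wobble = integer(0),
                      fraction = numeric(0)))
  wob <- vapply(sub$sequence, function(s) {
    st <- tryCatch(acceptorStemPairs(s), error = function(e) NULL)
    !is.null(st) && detectWobble(st, 4L)$is_G4U69
  }, logical(1), USE.NAMES = FALSE)
  agg <- stats::aggregate(cbind(n_total = rep(1L, nrow(sub)), n_wobble = wob),
                          by = list(organism = sub$organism), FUN = sum)
  data.frame(organism = agg$organism, isotype = isotype,
             n_total = as.integer(agg$n_total),
             n_wobble = as.integer(agg$n_wobble),
             fraction = 100 * agg$n_wobble / agg$n_total,
             stringsAsFactors = FALSE)
}

#' Co-occurrence of tRNA wobble enrichment with deacylase presence
#'
#' Classifies each organism as "enriched" when its G4:U69 fraction for the
#' surveyed isotype is at least `enrich_threshold` percent, crosses that
#' with the ATD presence/absence table, and reports the 2x2 table, the
#' concordance (fraction of organisms on the diagonal), and the two-sided
#' Fisher exact p-value.
#'
#' @param enrichment data.frame from [wobbleEnrichment()].
#' @param presence named logical vector (organism -> ATD present).
#' @param enrich_threshold percent; default 10.
#' @return list with `table` (2x2), `concordance`, `fisher_p`, `n`.
#' @export
cooccurrence <- function(enrichment, presence, enrich_threshold = 10) {
  orgs <- intersect(enrichment$organism, names(presence))
  if (length(orgs) < 2)
    stop("co-occurrence needs >= 2 organisms with both enrichment and ",
         "presence data")
  enr <- enrichment$fraction[match(orgs, enrichment$organism)] >=
    enrich_threshold
  atd <- as.logical(presence[orgs])
  tab <- table(factor(enr, levels = c(TRUE, FALSE)),
               factor(atd, levels = c(TRUE, FALSE)),
               dnn = c("enriched", "atd_present"))
  conc <- (tab[1, 1] + tab[2, 2]) / length(orgs)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(table = tab, concordance = as.numeric(conc), fisher_p = p,
       n = length(orgs))
}

#' Acceptor-stem consensus across a gene set
#'
#' For each of the seven stem pairs, the modal base pair and its frequency.
#' In tRNA-Thr(G4:U69) sets from chordates the first five pairs are
#' invariant or highly conserved.
#'
#' @param genes data.frame as from [readTRNATable()] (>= 1 row).
#' @return data.frame with columns `pair_index`, `modal_pair`, `frequency`.
#' @export
acceptorConsensus <- function(genes) {
  if (!nrow(genes)) stop("no genes supplied")
  stems <- lapply(genes$sequence, acceptorStemPairs)
  out <- lapply(1:7, function(i) {
    pairs <- vapply(stems, function(st)
      paste0(st$five_prime_base[i], ":", st$three_prime_base[i]), character(1))
    tt <- sort(table(pairs), decreasing = TRUE)
    data.frame(pair_index = i, modal_pair = names(tt)[1],
               frequency = as.numeric(tt[1]) / length(pairs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
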