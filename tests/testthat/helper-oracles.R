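## Independent oracles. Each re-derives its quantity by brute force along a
## different code path than the implementation it checks.

## Codon-walking NMD oracle: builds the spliced sequence base by base,
## locates the annotated/built CDS start by scanning the per-base genomic
## position map, walks codons with substr() to the first stop, and counts
## the bases between the stop and the first base of the last exon.
oracle_nmd <- function(aset, tx, genome, threshold = 50) {
  ex <- tx_exons(aset, tx)
  chrom <- as.character(GenomicRanges::seqnames(ex))[1]
  minus <- as.character(GenomicRanges::strand(ex))[1] == "-"
  gpos <- unlist(lapply(seq_along(ex), function(i)
    seq(GenomicRanges::start(ex)[i], GenomicRanges::end(ex)[i])))
  chars <- strsplit(as.character(genome[[chrom]]), "")[[1]][gpos]
  if (minus) {
    gpos <- rev(gpos)
    chars <- rev(chartr("ACGT", "TGCA", chars))
  }
  total <- length(chars)
  n_ex <- length(ex)
  cds <- tx_cds(aset, tx)
  if (!length(cds)) return(list(has_cds = FALSE, is_nmd = FALSE))
  first_cds_base <- if (minus) max(GenomicRanges::end(cds)) else
    min(GenomicRanges::start(cds))
  start_idx <- which(gpos == first_cds_base)
  seqstr <- paste(chars, collapse = "")
  pos <- start_idx
  stop_last <- NA
  while (pos + 2 <= total) {
    if (substr(seqstr, pos, pos + 2) %in% c("TAA", "TAG", "TGA")) {
      stop_last <- pos + 2
      break
    }
    pos <- pos + 3
  }
  if (is.na(stop_last)) return(list(has_cds = TRUE, is_nmd = FALSE))
  last_exon_len <- if (minus) GenomicRanges::width(ex)[1] else
    GenomicRanges::width(ex)[n_ex]
  last_junction <- total - last_exon_len + 1
  between <- last_junction - stop_last - 1
  list(has_cds = TRUE, is_nmd = n_ex >= 2 && between > threshold,
       between = between)
}

## Exact piecewise-exponential solution of dR/dt = rt*rn*v - k R with
## piecewise-constant schedules.
oracle_ode <- function(params, t_grid, R0 = NULL) {
  k <- params$k_dr
  val <- function(sched, t) sched$values[findInterval(t, sched$breaks)]
  if (is.null(R0))
    R0 <- val(params$r_t_schedule, t_grid[1]) *
      val(params$r_n_schedule, t_grid[1]) * params$v_sr / k
  brk <- sort(unique(c(params$r_t_schedule$breaks,
                       params$r_n_schedule$breaks)))
  brk <- brk[brk > t_grid[1] & brk < t_grid[length(t_grid)]]
  bounds <- c(t_grid[1], brk, t_grid[length(t_grid)])
  R <- numeric(length(t_grid))
  state <- R0
  for (s in seq_len(length(bounds) - 1)) {
    a <- bounds[s]; b <- bounds[s + 1]
    ss <- val(params$r_t_schedule, a) * val(params$r_n_schedule, a) *
      params$v_sr / k
    sel <- which(t_grid >= a & t_grid <= b)
    R[sel] <- ss + (state - ss) * exp(-k * (t_grid[sel] - a))
    state <- ss + (state - ss) * exp(-k * (b - a))
  }
  R
}

## One-sided (greater) Fisher p by direct hypergeometric summation over all
## tables with the observed margins and a top-left cell >= the observed one.
oracle_fisher_greater <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  if (m == 0 || n == 0 || kk == 0 || sum(tab[, 2]) == 0) return(1)
  amax <- min(m, kk)
  num <- 0; den <- 0
  for (x in max(0, kk - n):amax) {
    term <- choose(m, x) * choose(n, kk - x)
    den <- den + term
    if (x >= a) num <- num + term
  }
  num / den
}

## Exact two-sided Kendall p for tie-free data by full enumeration of the
## n! equally likely rankings.
oracle_kendall_p <- function(x, y) {
  n <- length(x)
  tau_of <- function(a, b) {
    s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      s <- s + sign(a[j] - a[i]) * sign(b[j] - b[i])
    s / choose(n, 2)
  }
  obs <- abs(tau_of(x, y))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  taus <- vapply(perms(seq_len(n)), function(p) tau_of(x, y[p]), numeric(1))
  mean(abs(taus) >= obs - 1e-12)
}

## Two-sided permutation p for the Pearson correlation over all orderings.
oracle_pearson_perm_p <- function(x, y) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  obs <- abs(cor(x, y))
  rs <- vapply(perms(seq_len(n)), function(p) cor(x, y[p]), numeric(1))
  mean(abs(rs) >= obs - 1e-12)
}

## Per-base mean conservation: expands intervals and track to base vectors.
oracle_mean_conservation <- function(intervals, track) {
  vals <- c()
  for (i in seq_along(intervals)) {
    for (b in GenomicRanges::start(intervals)[i]:
             GenomicRanges::end(intervals)[i]) {
      hit <- which(as.character(GenomicRanges::seqnames(track)) ==
                     as.character(GenomicRanges::seqnames(intervals))[i] &
                   GenomicRanges::start(track) <= b &
                   GenomicRanges::end(track) >= b)
      if (length(hit)) vals <- c(vals, track$score[hit[1]])
    }
  }
  if (!length(vals)) NA_real_ else mean(vals)
}
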