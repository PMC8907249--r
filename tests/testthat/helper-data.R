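# small dataset builders shared across tests

toy_cr <- function() {
  # 4 records used by the hand life-table computations
  cr_dataset(time = c(1, 2, 2, 3), status = c(0, 1, 0, 2),
             x = matrix(0, 4, 1), k = 4)
}

# a censoring_survival object with prescribed G values (for weight tests)
manual_G <- function(surv) {
  structure(list(time = seq_along(surv) - 1L, surv = surv,
                 at_risk = rep(NA_integer_, length(surv)),
                 censored = rep(NA_integer_, length(surv))),
            class = "censoring_survival")
}

# brute-force competing-risks concordance: exhaustive ordered-pair
# enumeration, unweighted (valid oracle when the data are uncensored)
brute_cindex <- function(time, status, marker, t) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (status[i] != 1L || time[i] > t) next
    for (j in seq_len(n)) {
      if (j == i) next
      if (!(time[i] < time[j] || status[j] == 2L)) next
      den <- den + 1
      if (marker[i] > marker[j]) num <- num + 1
      else if (marker[i] == marker[j]) num <- num + 0.5
    }
  }
  if (den == 0) NA_real_ else num / den
}
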