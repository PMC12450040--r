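# shared fixtures built in code

protocol_grid <- c(0, 30, 60, 120, 240, 360, 480, 720)

# write a custom group table and read it back through the package parser
make_group_table <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  read_group_table(path)
}

fatty_acid <- function(n_ch2, molar_mass, density) {
  des_component(sprintf("acid_C%d", n_ch2 + 2),
                c(CH3 = 1, CH2 = n_ch2, COOH = 1),
                molar_mass = molar_mass, density = density)
}

# brute-force per-occurrence accumulation oracle for the HvK expressions
hansen_oracle <- function(groups, counts, v) {
  fd <- 0; fp2 <- 0; eh <- 0
  for (g in names(counts)) {
    row <- groups[groups$group == g, ]
    for (i in seq_len(counts[[g]])) {
      fd <- fd + row$F_d
      fp2 <- fp2 + row$F_p^2
      eh <- eh + row$E_h
    }
  }
  c(fd / v, sqrt(fp2) / v, sqrt(eh / v))
}
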