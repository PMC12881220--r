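test_that("oxygen-to-power conversion is the 20 J/mL line through zero", {
  expect_equal(o2_to_watts(1), 20)
  expect_equal(o2_to_watts(0), 0)
  expect_equal(o2_to_watts(0.05), 1)
  # linear scaling oracle on a grid
  x <- seq(0, 2, by = 0.25)
  expect_equal(o2_to_watts(x), 20 * x)
  expect_error(o2_to_watts(-1), "non-negative")
})

test_that("Boltzmann correction multiplies by exp(Ea/kT) and round-trips", {
  expect_equal(temperature_correct(1, 300, Ea = 0), 1)
  # independent scalar computation of the exponent
  k <- 8.617333e-5
  expect_equal(temperature_correct(1, 307.75, Ea = 0.63),
               exp(0.63 / (k * 307.75)))
  expect_gt(temperature_correct(1, 307.75, Ea = 0.63), 2.0e10 * 0.9)
  # monotone in Ea and in 1/T
  ea <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(temperature_correct(1, 300, Ea = ea)) > 0))
  Ts <- seq(270, 320, by = 10)
  expect_true(all(diff(temperature_correct(1, Ts, Ea = 0.63)) < 0))
  # correct then un-correct returns the original rate
  r <- c(0.01, 1, 50)
  corr <- temperature_correct(r, 290, Ea = 0.63)
  expect_equal(corr * exp(-0.63 / (k * 290)), r, tolerance = 1e-12)
  expect_error(temperature_correct(1, -5), "positive")
})

test_that("temperature resolution fills endotherm defaults only", {
  res <- resolve_temperature(
    c("endo_vertebrate", "endo_vertebrate", "ecto_vertebrate",
      "ecto_invertebrate"),
    c(NA, NA, 280, NA),
    class = c("mammal", "bird", NA, NA))
  expect_equal(res$temperature_K[1], 310.15)
  expect_equal(res$temperature_K[2], 312.15)
  expect_equal(res$temperature_K[3], 280)
  expect_equal(res$drop, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("table ingestion converts units, fills defaults, drops bad rows", {
  tab <- make_record_table()
  rt <- read_rate_table(tab)
  # the Mus record with missing T gets the mammal default
  expect_true(all(rt$temperature_K > 0))
  mus <- rt[rt$genus == "Mus" & !is.finite(rt$temperature_C), ]
  expect_equal(mus$temperature_K, 310.15)
  # the bird default
  expect_equal(rt$temperature_K[rt$genus == "Corvus"], 312.15)
  # the mlO2 record became Watts
  apis <- rt[rt$genus == "Apis", ]
  expect_equal(sort(apis$rate_W_or_kgyr), sort(c(0.001, 0.002 * 20)))
  # the ectotherm with missing temperature (none here) and invalid rows drop
  tab2 <- tab
  tab2$temperature_C[tab2$genus == "Rana"] <- NA
  rt2 <- suppressMessages(read_rate_table(tab2))
  expect_false("Rana" %in% rt2$genus)
  # producer metabolism is rejected
  tab3 <- tab
  tab3$metabolic_group[1] <- "producer"
  expect_error(read_rate_table(tab3), "out of scope")
})

test_that("genus means average on the log scale per genus and rate kind", {
  # two records of one genus with log-rates {2, 4} -> mean 3
  tab <- data.frame(
    genus = c("A", "A", "B"), family = NA, order = NA,
    metabolic_group = "ecto_invertebrate", rate_kind = "metabolism",
    rate_corrected = c(exp(2), exp(4), exp(1)),
    mass_kg = c(exp(-1), exp(-3), exp(0)),
    stringsAsFactors = FALSE)
  gm <- genus_means(tab)
  expect_equal(nrow(gm), 2)
  expect_equal(gm$log_rate_corrected[gm$genus == "A"], 3)
  expect_equal(gm$log_mass[gm$genus == "A"], -2)
  expect_equal(gm$log_rate_corrected[gm$genus == "B"], 1)  # identity

  # production uses base-10 logs
  tabp <- transform(tab, rate_kind = "production",
                    rate_corrected = c(100, 10000, 10))
  gmp <- genus_means(tabp)
  expect_equal(gmp$log_rate_corrected[gmp$genus == "A"], 3)
  expect_equal(gmp$log_base, rep("log10", 2))

  # brute-force per-genus average on a random table
  set.seed(3)
  big <- data.frame(
    genus = sample(paste0("g", 1:8), 40, replace = TRUE), family = NA,
    order = NA, metabolic_group = "ecto_vertebrate",
    rate_kind = "metabolism", rate_corrected = exp(rnorm(40)),
    mass_kg = exp(rnorm(40)), stringsAsFactors = FALSE)
  gmb <- genus_means(big)
  for (g in unique(big$genus)) {
    expect_equal(gmb$log_rate_corrected[gmb$genus == g],
                 mean(log(big$rate_corrected[big$genus == g])))
  }
  # row count equals distinct (genus, rate_kind) pairs
  expect_equal(nrow(gmb), length(unique(big$genus)))

  # ambiguous group assignment errors
  amb <- tab
  amb$metabolic_group[2] <- "ecto_vertebrate"
  expect_error(genus_means(amb), "more than one metabolic group")
})
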