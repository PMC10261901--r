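# photoclock

Kinetic modelling of circadian-clock-controlled photosynthesis in tomato
(*Solanum lycopersicum*), for plant systems biologists who want to ask:
*what does changing light intensity do to the clock, and what does the
clock then do to photosynthesis?*

The core is a 29-variable ODE system. Six clock gene pairs — CL
(CCA1/LHY), P97 (PRR9/PRR7), P51 (PRR5/TOC1), EL (ELF4/LUX), GI, RVE8 —
are modelled as mRNA/protein pairs with Hill-type transcription
(exponent 2), first-order translation and degradation; eight further
states carry the evening complex (EC), the RVE8–LNK coactivator (RL),
the ZTL–GI complex with free ZTL, the three-state COP1 chain and HY5;
one state is the light-sensitive protein P with

    dP/dt = s_p · D · (1 − P) − d_p · f(I) · L · P

(L, D are the lights-on/off flags; P accumulates at night, is degraded
by day, and gates acute dawn inputs `q · f · P · L` into the
light-responsive promoters). Light intensity I (µmol m⁻² s⁻¹) enters
through the scale

    f(I) = I / (I_A·I² + I_B·I + I_C),

calibrated so f(100) = 1, f(62.5) = 0.8, f(187.5) ≈ 1.24. Four
photosynthetic gene pairs read the clock — *Lhcb1* activated by CL and
inhibited by GI, *psbA*/*RbcS1*/*atpA* repressed by CL — and the four
gas-exchange parameters (Pn, Gs, Ci, Tr) are algebraic Hill outputs of
CL, GI and the photosynthetic proteins:

    P_i = α_i + ( CL²/(K_i1²+CL²) + Σ_j X_j²/(H_ij²+X_j²) ) · K_i3²/(K_i2²+GI²)

Around the model the package provides: fixed-step classical RK4
simulation under light protocols (entrainment, free run, intensity
shifts), three period/phase estimators (multi-harmonic fit, Burg
maximum-entropy spectrum, Enright folding periodogram), a
simulated-annealing fitter with expression/period/phase cost windows,
robustness/sensitivity/Hopf reliability analysis, and a synthetic-data
generator for RT-qPCR-style expression series and diurnal gas-exchange
tables.

## Worked example

Simulate the two light-shift experiments (entrain at 100 µmol m⁻² s⁻¹,
then 48 h of LD 12:12 at low 62.5 or normal 187.5) and compare rhythm
parameters:

```r
library(photoclock)
p  <- default_params()
li <- run_protocol(p, "MI_to_LI", burn_in_days = 10, dt = 0.05,
                   treatment_days = 4)
ni <- run_protocol(p, "MI_to_NI", burn_in_days = 10, dt = 0.05,
                   treatment_days = 4)
rbind(LI = rhythm_table(li, genes = c("CL", "GI", "Lhcb1")),
      NI = rhythm_table(ni, genes = c("CL", "GI", "Lhcb1")))
```

```
      gene condition   period  period_sd      phase  phase_sd n
LI.1    CL    I=62.5 24.09403 0.16175878  0.4040129 1.9563412 3
LI.2    GI    I=62.5 23.96377 0.03604982 11.8291215 0.2140450 3
LI.3 Lhcb1    I=62.5 24.04715 0.07683497  5.7217554 0.9698934 3
NI.1    CL   I=187.5 23.35719 0.33897733  0.3565314 1.6349024 3
NI.2    GI   I=187.5 23.48126 0.37725075 10.8328602 0.3700567 3
NI.3 Lhcb1   I=187.5 23.58882 0.07979727  5.3599741 0.8545595 3
```

Reading the table: under low light every gene runs slower (estimated
period longer by ~0.5–0.7 h over the four treatment days) and peaks
later than under normal light — the Aschoff-rule behaviour the model
is calibrated to show. `period`/`phase` are the mean over the three
estimators (harmonic fit, MESA, Enright periodogram) with their SD;
phase is the ZT hour of the dominant peak of the first treatment
cycle. Measured on the settled second treatment day, the low-light
peak delays are 1.1–1.5 h for the morning-to-evening genes (P97, P51,
EL, GI, Lhcb1, psbA, RbcS1, atpA) and smaller for the two
dawn-anchored genes (CL, RVE8), mirroring the backward shift the
low-light condition is expected to produce.

Free-running rhythm and its constraint check:

```r
check_constraints(p, burn_in_days = 10, dt = 0.05)
```

```
 gene   period     phase period_ok phase_ok rhythmic
   CL 24.44485 15.933248      TRUE    FALSE     TRUE
  P97 24.42933  8.556766      TRUE     TRUE     TRUE
  P51 24.40206  7.858847      TRUE    FALSE     TRUE
   EL 24.32985 11.075339      TRUE     TRUE     TRUE
   GI 24.34973 11.252850      TRUE     TRUE     TRUE
 RVE8 24.17309  1.471293      TRUE     TRUE     TRUE
```

Every gene free-runs in the 24–28 h window. Four of the six peak-time
windows (CL 0–4, P97 6–10, P51 12–15, EL 10–15, GI 11–13, RVE8 0–3
ZT h) are met; the two reported FALSE rows are known limitations of
this calibration, discussed in the methods vignette — CL has a dawn
peak in-window, but its subjective-night shoulder is marginally higher
so the dominant-peak label lands there, and P51 peaks mid-morning
because in this compact re-derivation P51 shares its transcription
window with P97.

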