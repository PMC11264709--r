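# shared builders for the test suite; everything is generated in code

oneReactionDoc <- function() c(
  "# minimal one-reaction document",
  "species:",
  "  X0  init=1.0  boundary",
  "  S1  init=0.5",
  "parameters:",
  "  Vmax = 2.0",
  "  Km = 1.0",
  "reactions:",
  "  R1: X0 -> S1   rate = Vmax*X0/(Km + X0)")

uniUniReversibleModel <- function(Vf = 10, Keq = 2, KmS = 1, KmP = 4) {
  # Vr chosen from the Haldane identity Keq = Vf*KmP/(Vr*KmS)
  Vr <- Vf * KmP / (Keq * KmS)
  parseNativeModel(c(
    "species:",
    "  X0 init=1 boundary",
    "  A init=1",
    "  B init=1",
    "  Xout init=0 boundary",
    "parameters:",
    "  v0 = 1 role=other fixed",
    sprintf("  VfR = %.17g", Vf),
    sprintf("  VrR = %.17g", Vr),
    sprintf("  KeqR = %.17g  scope=Rrev", Keq),
    sprintf("  KmS_A = %.17g", KmS),
    sprintf("  KmP_B = %.17g", KmP),
    "  Vdrain = 4 role=forward_max_velocity",
    "  Kdrain = 1 role=binding_constant",
    "reactions:",
    "  Rsrc: X0 -> A   rate = v0",
    "  Rrev: A -> B    rate = (VfR*A/KmS_A - VrR*B/KmP_B)/(1 + A/KmS_A + B/KmP_B)",
    "  Rdrain: B -> Xout   rate = Vdrain*B/(Kdrain + B)"))
}

quickEqConfig <- function(generationCap = 30000) {
  equilibrationConfig(windowSize = 10, consecutiveWindows = 2,
                      fluxFraction = 0.8, slopeTol = 0.05, cvTol = 0.05,
                      generationCap = generationCap)
}
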