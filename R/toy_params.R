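# Frozen bridge-closure solutions for the synthetic class toys.
# Each entry holds the A8-A12 linker torsions (`link`, degrees), the
# bridge chi1 angles (`chi`), B8/B20 hinge torsions (`blink`) and the
# rigid placement of the B chain (`rigid`: rotation vector, then
# translation in Angstrom). The values are least-squares closure
# solutions, computed once, for the construction targets of each variant
# (A6-A11 and A7-B7 C-alpha distances per conformational class, Sg-Sg
# bonds at 2.04 A, dicarba C=C at 1.33 A with the core torsion at 0/180
# degrees, no steric clashes). They are constants of the generator, not
# tunable knobs.
#
# CLASS2 + trans_dicarba has no entry: closure of the elongated trans
# bridge onto the contracted Class 2 arrangement only converged with an
# order of magnitude more residual strain than every other variant, so
# the generator treats that combination as an infeasible bridge closure.

TOY_PARAMS <- list(
  CLASS1 = list(
    disulfide = list(
      link = c(psi8 = -48.7568, phi9 = -58.9175, psi9 = -32.8980,
               phi10 = 130.5502, psi10 = 7.0491, phi11 = 2.7097,
               psi11 = 71.9506, phi12 = -110.9383),
      chi = c(chiA6 = 101.9725, chiA11 = -133.5670, chiA7 = -91.5527,
              chiA20 = 4.6831, chiB7 = 111.8889, chiB19 = -127.4224),
      blink = c(phiB8 = -120, psiB8 = 135, phiB20 = -120, psiB20 = 135),
      rigid = c(0.084902, -1.851147, 2.761864,
                20.491638, 9.237315, 18.517771)),
    trans_dicarba = list(
      link = c(psi8 = -48.8722, phi9 = -58.6870, psi9 = -68.4551,
               phi10 = 149.7226, psi10 = 17.3993, phi11 = -11.4074,
               psi11 = 83.8585, phi12 = -114.6066),
      chi = c(chiA6 = 159.5071, chiA11 = -60.2420, chiA7 = -79.4252,
              chiA20 = -1.9088, chiB7 = 55.6011, chiB19 = -145.4930),
      blink = c(phiB8 = -120, psiB8 = 135, phiB20 = -120, psiB20 = 135),
      rigid = c(-0.683566, -1.948223, 2.151246,
                10.303870, 5.572964, 26.401073)),
    cis_dicarba = list(
      link = c(psi8 = -48.3614, phi9 = -58.2188, psi9 = -65.1501,
               phi10 = 171.5314, psi10 = 15.4682, phi11 = -87.3101,
               psi11 = -17.4462, phi12 = -83.1329),
      chi = c(chiA6 = 115.1045, chiA11 = 104.1377, chiA7 = -23.4275,
              chiA20 = 77.7083, chiB7 = 11.7275, chiB19 = -124.4306),
      blink = c(phiB8 = -120, psiB8 = 135, phiB20 = -120, psiB20 = 135),
      rigid = c(1.115683, 8.991412, -2.733542,
                14.250812, -8.005855, 14.834157))),
  CLASS2 = list(
    cis_dicarba = list(
      link = c(psi8 = -70.2950, phi9 = -49.2087, psi9 = -25.4829,
               phi10 = 112.7990, psi10 = 126.4310, phi11 = 169.5507,
               psi11 = 23.9001, phi12 = -30.2670),
      chi = c(chiA6 = 178.0934, chiA11 = 108.3913, chiA7 = -111.6992,
              chiA20 = 75.5475, chiB7 = -179.2086, chiB19 = -146.2686),
      blink = c(phiB8 = -120, psiB8 = 135, phiB20 = -120, psiB20 = 135),
      rigid = c(-0.631408, -1.964391, 8.958697,
                14.286303, 25.135753, 15.130286)),
    disulfide = list(
      link = c(psi8 = -76.9726, phi9 = -58.9599, psi9 = -134.1341,
               phi10 = -129.0211, psi10 = 148.8222, phi11 = -145.5065,
               psi11 = -25.9416, phi12 = 76.2809),
      chi = c(chiA6 = -102.3425, chiA11 = -105.7147, chiA7 = -90.1698,
              chiA20 = -64.7717, chiB7 = -39.5767, chiB19 = -107.8721),
      blink = c(phiB8 = -120, psiB8 = 135, phiB20 = -120, psiB20 = 135),
      rigid = c(2.464424, 1.827941, -2.117024,
                -11.379939, 8.466900, 19.623468))))
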