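# Cohort reference phylogeny, indented dialect (see ?parsePhylogeny).
# One node per line; depth = leading spaces / 2; fields separated by ';'.
# Branch mutations are differences from the mitochondrial reference frame
# accumulated root-to-tip, written in the shorthand branch dialect.  Only
# non-synonymous changes are encoded, so nodes with no non-synonymous marker
# among these samples collapse onto their parent (e.g. the shared U ancestry
# of U6a1a1 and K1a).  Control sample I (a non-carrier of 14568) sits inside
# J1c2, separating the two carrier lineages 11 and 12.
H ; hg=H
  F1 ; muts=3700,13759
  H26a ; hg=H26a
    F2 ; muts=3700
  H66 ; hg=H66
    F3 ; muts=14495
  H1c1 ; hg=H1c1
    F4 ; muts=14568
  H10 ; hg=H10
    F5 ; muts=3733,9091
  N ; hg=N ; muts=14766
    I5a ; hg=I5a ; muts=10398
      F15 ; muts=5074,13780,14482A
    X2b ; hg=X2b ; muts=8393,13708,13966
      F14 ; muts=3733,7859,11084
    L2a1 ; hg=L2a1 ; muts=8701,9053,10398
      F16 ; muts=10663
    R ; hg=R
      U6a1a1 ; hg=U6a1a1 ; muts=4172A,7805,14927,15221
        F6 ; muts=14568
      K1a ; hg=K1a ; muts=9055,10398,14798
        F7 ; muts=7299,13759,14568
      JT ; hg=JT ; muts=4216
        J ; hg=J ; muts=10398,13708,15452A
          J2b ; hg=J2b ; muts=15257
            J2b1 ; hg=J2b1
              F13 ; muts=4171A,7632,15812
          J1c ; hg=J1c ; muts=14798
            F10 ; muts=14482A
            J1c3 ; hg=J1c3 ; muts=13934
              F8 ; muts=14459
              J1c3e1 ; hg=J1c3e1 ; muts=13145,14502
                F9 ; muts=3733C
            J1c2 ; hg=J1c2
              F12 ; muts=14325,14568
              J1c2e ; hg=J1c2e
                F11 ; muts=14568
              I
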