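#!/usr/bin/env python
"""Exact-rational oracle for the two-library exact conditional test.

Reads whitespace-separated lines "x y n1 n2" on stdin and prints, one per
line, the two-sided p-value min(1, 2*min(P(Y<=y|x), P(Y>=y|x))) computed in
exact rational arithmetic with

    p(k | x) = r^k * C(x+k, k) / (1+r)^(x+k+1),   r = n2/n1,

then rounded once to the nearest double on output. Independent of any R
code; used only as a test oracle.
"""
import sys
from fractions import Fraction
from math import comb


def two_sided_p(x, y, n1, n2):
    r = Fraction(n2, n1)
    one_plus_r = 1 + r
    lower = Fraction(0)
    mass_below = Fraction(0)  # P(Y <= y-1 | x)
    for k in range(y + 1):
        term = r**k * comb(x + k, k) / one_plus_r ** (x + k + 1)
        lower += term
        if k < y:
            mass_below += term
    upper = 1 - mass_below  # P(Y >= y | x), exact
    p = 2 * min(lower, upper)
    return min(p, Fraction(1))


def main():
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        x, y, n1, n2 = (int(v) for v in line.split())
        print(repr(float(two_sided_p(x, y, n1, n2))))


if __name__ == "__main__":
    main()
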