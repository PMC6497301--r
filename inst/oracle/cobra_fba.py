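#!/usr/bin/env python
"""Independent FBA oracle: read a model in the package's JSON dialect,
solve max-biomass FBA with cobrapy/GLPK, print the optimum."""
import json
import sys

import cobra
from cobra import Metabolite, Model, Reaction


def main(path):
    with open(path) as fh:
        j = json.load(fh)
    m = Model(j.get("id", "model"))
    mets = {mid: Metabolite(mid) for mid in j["metabolites"]}
    rxns = []
    for r in j["reactions"]:
        rx = Reaction(r["id"])
        rx.lower_bound = r["lb"]
        rx.upper_bound = r["ub"]
        rxns.append(rx)
    m.add_reactions(rxns)
    for r, rx in zip(j["reactions"], rxns):
        rx.add_metabolites({mets[k]: v for k, v in r["mets"].items()})
    m.objective = j["objective"]
    sol = m.optimize()
    print(sol.status)
    print(repr(sol.objective_value))


if __name__ == "__main__":
    main(sys.argv[1])
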