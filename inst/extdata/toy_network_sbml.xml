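<?xml version="1.0" encoding="UTF-8"?>
<!-- SBML L3+FBC transcription of the 9-reaction worked-example fixture -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>
      <species id="B" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>
      <species id="C" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb0" value="0" constant="true"/>
      <parameter id="ub1000" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="R1" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
        <listOfProducts><speciesReference species="A" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="R2" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
        <listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="R3" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
        <listOfProducts><speciesReference species="A" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="R4" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
        <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
      <reaction id="R5" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
        <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="C" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="R6" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
        <listOfReactants><speciesReference species="B" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="C" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="R7" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
        <listOfReactants><speciesReference species="B" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="A" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="R8" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
        <listOfReactants><speciesReference species="B" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
      <reaction id="R9" reversible="false" fast="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub1000">
        <listOfReactants><speciesReference species="C" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
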