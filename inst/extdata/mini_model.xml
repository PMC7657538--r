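<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="mini_model">
    <listOfSpecies>
      <species id="glc__D_e" compartment="e" boundaryCondition="false"/>
      <species id="glc__D_c" compartment="c" boundaryCondition="false"/>
      <species id="g6p_c" compartment="c" boundaryCondition="false"/>
      <species id="f6p_c" compartment="c" boundaryCondition="false"/>
      <species id="pyr_c" compartment="c" boundaryCondition="false"/>
      <species id="atp_c" compartment="c" boundaryCondition="false"/>
      <species id="adp_c" compartment="c" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_EX_glc__D_e" reversible="true">
        <listOfReactants>
          <speciesReference species="glc__D_e"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_GLCt" reversible="false">
        <listOfReactants>
          <speciesReference species="glc__D_e"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="glc__D_c"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_HEX1" reversible="false">
        <listOfReactants>
          <speciesReference species="glc__D_c"/>
          <speciesReference species="atp_c"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="g6p_c"/>
          <speciesReference species="adp_c"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_PGI" reversible="true">
        <listOfReactants>
          <speciesReference species="g6p_c"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="f6p_c"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_GLYC" reversible="false">
        <listOfReactants>
          <speciesReference species="f6p_c"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="pyr_c"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
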