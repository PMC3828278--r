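<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic test fixture: irreversible two-step chain X0 -> S1 -> (sink)
     with one reaction-local parameter, a function definition and an
     assignment rule. Not derived from any published model. -->
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="two_step_chain_synthetic">
    <listOfFunctionDefinitions>
      <functionDefinition id="mass_action">
        <math xmlns="http://www.w3.org/1998/Math/MathML">
          <lambda>
            <bvar><ci>k</ci></bvar>
            <bvar><ci>s</ci></bvar>
            <apply><times/><ci>k</ci><ci>s</ci></apply>
          </lambda>
        </math>
      </functionDefinition>
    </listOfFunctionDefinitions>
    <listOfCompartments>
      <compartment id="cell" size="1"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="X0" compartment="cell" initialConcentration="1"
               boundaryCondition="true"/>
      <species id="S1" compartment="cell" initialAmount="0"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k1" value="2"/>
      <parameter id="k2_scale" value="2"/>
      <parameter id="k2_eff" value="0"/>
    </listOfParameters>
    <listOfRules>
      <assignmentRule variable="k2_eff">
        <math xmlns="http://www.w3.org/1998/Math/MathML">
          <apply><times/><ci>k2_scale</ci><cn type="integer">2</cn></apply>
        </math>
      </assignmentRule>
    </listOfRules>
    <listOfReactions>
      <reaction id="step1" reversible="false">
        <listOfReactants>
          <speciesReference species="X0" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="S1" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><ci>mass_action</ci><ci>k1</ci><ci>X0</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="step2" reversible="false">
        <listOfReactants>
          <speciesReference species="S1" stoichiometry="1"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>kcat</ci><ci>k2_eff</ci><ci>S1</ci></apply>
          </math>
          <listOfParameters>
            <parameter id="kcat" value="1"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
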