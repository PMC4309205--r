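<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1" xmlns:qual="http://www.sbml.org/sbml/level3/version1/qual/version1" qual:required="true">
  <model id="logimc_model">
    <qual:listOfQualitativeSpecies>
      <qual:qualitativeSpecies qual:id="I" qual:maxLevel="1" qual:constant="true"/>
      <qual:qualitativeSpecies qual:id="A" qual:maxLevel="1" qual:constant="false"/>
      <qual:qualitativeSpecies qual:id="B" qual:maxLevel="1" qual:constant="false"/>
    </qual:listOfQualitativeSpecies>
    <qual:listOfTransitions>
      <qual:transition qual:id="tr_A">
        <qual:listOfInputs>
          <qual:input qual:id="in_A_I" qual:qualitativeSpecies="I" qual:transitionEffect="none" qual:thresholdLevel="1" qual:sign="positive"/>
          <qual:input qual:id="in_A_B" qual:qualitativeSpecies="B" qual:transitionEffect="none" qual:thresholdLevel="1" qual:sign="negative"/>
        </qual:listOfInputs>
        <qual:listOfOutputs>
          <qual:output qual:id="out_A" qual:qualitativeSpecies="A" qual:transitionEffect="assignmentLevel"/>
        </qual:listOfOutputs>
        <qual:listOfFunctionTerms>
          <qual:defaultTerm qual:resultLevel="0"/>
          <qual:functionTerm qual:resultLevel="1">
            <math xmlns="http://www.w3.org/1998/Math/MathML">
              <apply><and/><apply><eq/><ci>I</ci><cn type="integer">1</cn></apply><apply><eq/><ci>B</ci><cn type="integer">0</cn></apply></apply>
            </math>
          </qual:functionTerm>
        </qual:listOfFunctionTerms>
      </qual:transition>
      <qual:transition qual:id="tr_B">
        <qual:listOfInputs>
          <qual:input qual:id="in_B_A" qual:qualitativeSpecies="A" qual:transitionEffect="none" qual:thresholdLevel="1" qual:sign="negative"/>
        </qual:listOfInputs>
        <qual:listOfOutputs>
          <qual:output qual:id="out_B" qual:qualitativeSpecies="B" qual:transitionEffect="assignmentLevel"/>
        </qual:listOfOutputs>
        <qual:listOfFunctionTerms>
          <qual:defaultTerm qual:resultLevel="0"/>
          <qual:functionTerm qual:resultLevel="1">
            <math xmlns="http://www.w3.org/1998/Math/MathML">
              <apply><eq/><ci>A</ci><cn type="integer">0</cn></apply>
            </math>
          </qual:functionTerm>
        </qual:listOfFunctionTerms>
      </qual:transition>
    </qual:listOfTransitions>
  </model>
</sbml>
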