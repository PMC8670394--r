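# Medical domain knowledge base: medical data-analysis tasks, the medical
# rendering of the CRISP-DM stages, and the data characteristics observed
# on acid-base state cohorts.

SUBCLASSOF	MedicalDataAnalysisTask	DataAnalysisTask
SUBCLASSOF	ConsistencyAnalysis	MedicalDataAnalysisTask
SUBCLASSOF	MedicalData	INPUT
SUBCLASSOF	Continuous	DataCharacteristic
SUBCLASSOF	Missing_not_Random	DataCharacteristic

# the DM objective the task requirement converts to
DATAPROP	ConsistencyAnalysis	hasDMObjective	consistency_of_parameter_dynamics	string

# the five stages of the medical analysis workflow
SUBCLASSOF	TaskUnderstanding	Stage
SUBCLASSOF	DataProcessing	Modelling
RESTRICTION	TaskUnderstanding	stageOf	some	MedicalDataAnalysisTask
RESTRICTION	DataUnderstanding	stageOf	some	MedicalDataAnalysisTask
RESTRICTION	DataPreparation	stageOf	some	MedicalDataAnalysisTask
RESTRICTION	DataProcessing	stageOf	some	MedicalDataAnalysisTask
RESTRICTION	Evaluation	stageOf	some	MedicalDataAnalysisTask
RESTRICTION	TaskUnderstanding	hasPostprocess	some	DataUnderstanding
RESTRICTION	DataUnderstanding	postprocessOf	some	TaskUnderstanding

# task-understanding sub-process: task objective -> DM objective lookup
SUBCLASSOF	ObjectiveConversion	Process
RESTRICTION	ObjectiveConversion	subprocessOf	some	TaskUnderstanding

# the modelling process of the consistency-analysis workflow
RESTRICTION	ConsistencyModelling	subprocessOf	some	DataProcessing
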